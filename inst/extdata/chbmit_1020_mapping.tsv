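# Default CHB-MIT channel -> 10-20 electrode assignment (editable).
# The CHB-MIT montage is bipolar; each channel is assigned one representative
# scalp electrode so that 22 of the 23 recorded channels cover the package's
# 22-electrode set. This is a documented convention, not ground truth: the
# public dataset does not state which 22 channels its users keep. Edit this
# file (or pass your own table) to change the assignment.
chbmit	electrode
FP1-F7	FP1
F7-T7	F7
T7-P7	T7
P7-O1	P7
FP1-F3	F3
F3-C3	C3
C3-P3	P3
P3-O1	O1
FP2-F4	FP2
F4-C4	F4
C4-P4	C4
P4-O2	P4
FP2-F8	F8
F8-T8	T8
T8-P8	P8
P8-O2	O2
FZ-CZ	FZ
CZ-PZ	CZ
P7-T7	PZ
T7-FT9	FT9
FT9-FT10	FCZ
FT10-T8	FT10
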