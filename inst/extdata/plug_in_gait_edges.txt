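# Default anatomical edge table for the 39-marker Plug-in Gait body graph.
# One unordered label pair per line. This table is the package's own
# construction (segment chains joined at shared landmarks); edit or replace
# it to use a different topology.
# head
LFHD RFHD
LFHD LBHD
RFHD RBHD
LBHD RBHD
# head-torso
LBHD C7
RBHD C7
# torso
C7 CLAV
C7 T10
C7 RBAK
CLAV STRN
T10 STRN
T10 RBAK
# shoulders
C7 LSHO
C7 RSHO
CLAV LSHO
CLAV RSHO
# left arm chain
LSHO LUPA
LUPA LELB
LELB LFRM
LFRM LWRA
LFRM LWRB
LWRA LWRB
LWRA LFIN
LWRB LFIN
# right arm chain
RSHO RUPA
RUPA RELB
RELB RFRM
RFRM RWRA
RFRM RWRB
RWRA RWRB
RWRA RFIN
RWRB RFIN
# pelvis ring
LASI RASI
LPSI RPSI
LASI LPSI
RASI RPSI
# torso-pelvis
T10 LPSI
T10 RPSI
STRN LASI
STRN RASI
# left leg chain
LASI LTHI
LTHI LKNE
LKNE LTIB
LTIB LANK
LANK LHEE
LANK LTOE
LHEE LTOE
# right leg chain
RASI RTHI
RTHI RKNE
RKNE RTIB
RTIB RANK
RANK RHEE
RANK RTOE
RHEE RTOE
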