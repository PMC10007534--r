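# Racket-to-body attachment edges, right-handed grip.
# The handle-bottom marker connects to the dominant-hand wrist and finger
# markers. For a left-handed player the R* labels are swapped to L* at
# attachment time.
RKT_HANDLE_BOT RWRA
RKT_HANDLE_BOT RWRB
RKT_HANDLE_BOT RFIN
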