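# Trial event timing, fixed by the task structure (ms from pre-cue onset):
# 400 ms pre-cue -> 1000 ms ISI -> 600 ms sound array -> 1000 ms delay ->
# 400 ms retro-cue -> 1000 ms delay -> 600 ms probe. Analysis windows quoted
# "post retro-cue onset" are shifted by +3000 ms into epoch time.
RETROCUE_ONSET_MS <- 3000
PROBE_ONSET_MS <- 4400
PROBE_DURATION_MS <- 600
RESPONSE_WINDOW_MS <- 1500  # counted from probe offset
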