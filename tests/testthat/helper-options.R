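# never truncate the run on accumulated failures: the acceptance battery
# deliberately reports known-red model-conditional checks, and the rest of
# the suite must still execute after them
options(testthat.progress.max_fails = 1000)
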