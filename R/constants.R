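# Shared vocabulary constants.

ENV_VARIABLES <- c("depth", "temperature", "tds", "conductivity",
                   "salinity", "do", "ph", "chlorophyll_a")

TAXON_GROUPS <- c("fish", "mollusk", "crustacean")
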