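# Deterministic substream seed derived from a master seed and a string key
# (e.g. a canonical community notation). Polynomial string hash folded with
# the master seed, kept inside the 32-bit integer range so set.seed() takes
# it directly. Adding or removing communities from a survey therefore never
# shifts the random draws of the others.
.substreamSeed <- function(master, key) {
    mod <- 2147483647
    h <- as.numeric(master) %% mod
    for (code in utf8ToInt(key)) {
        h <- (h * 131 + code) %% mod
    }
    as.integer(h)
}
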