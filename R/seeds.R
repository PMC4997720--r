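# Deterministic seed derivation: all randomness flows from one master seed
# through named child streams, so strategy-internal resampling never perturbs
# the comparison loop's bootstrap sequence and any grid point or replicate can
# be recomputed in isolation.

M31 <- 2147483647  # 2^31 - 1; keeps every derived seed a valid 32-bit integer

child_seed <- function(master, a = 0L, b = 0L) {
  s <- as.double(master) %% M31
  s <- (s * 48271) %% M31
  s <- (s + as.double(a) * 7919 + as.double(b)) %% M31
  s <- (s * 48271) %% M31
  as.integer(s %% (M31 - 1) + 1)
}

# stable small hash of a strategy name, so per-replicate strategy streams
# depend on the strategy and not on whether it sits in slot A or B
name_hash <- function(name) {
  sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 100003L
}
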