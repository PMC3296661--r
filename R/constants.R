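# Shared lookup tables. Allele sets are handled as bitmask keys
# (A=1, C=2, G=4, T=8) so classification reduces to integer arithmetic.

.BASES <- c("A", "C", "G", "T")

.IUPAC_PAIRS <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

# bitmask key -> IUPAC code (NA for invalid / >2-base keys)
.KEY_CODE <- c("A", "C", "M", "G", "R", "S", NA, "T", "W", "Y", NA, "K",
               NA, NA, NA)

# bitmask key -> number of alleles (0 marks >2-base keys)
.POPCNT <- c(1L, 1L, 2L, 1L, 2L, 2L, 0L, 1L, 2L, 2L, 0L, 2L, 0L, 0L, 0L)

# bitmask key -> base, for singleton keys only
.KEY_BASE <- c("A", "C", NA, "G", NA, NA, NA, "T", rep(NA, 7L))
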