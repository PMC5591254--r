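# Gene symbols from mixed-source TSVs differ in case/whitespace; all matching
# goes through this canonical form.
canonicalGene <- function(x) toupper(trimws(as.character(x)))

# match gene identifiers case-insensitively after trimming; returns integer
# index into `table` (NA where absent)
matchGenes <- function(x, table) match(canonicalGene(x), canonicalGene(table))

stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)

# deterministic sub-seed derivation: keeps every stream tied to one user seed
# while decoupling the draws of different generator stages (32-bit safe)
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
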