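# shared small helpers

# sample DNA at a target G+C fraction
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# encode a protein string as 0-based residue indices (-1 for X/unknown)
encode_protein <- function(protein) {
  idx <- match(strsplit(protein, "", fixed = TRUE)[[1]], AA_ALPHABET)
  idx[is.na(idx)] <- 0L
  as.integer(idx - 1L)
}

# 1-based inclusive interval length
interval_len <- function(start, end) end - start + 1L

# distance between two 1-based inclusive intervals (0 if they overlap/touch)
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

stopifnot_scalar_interval <- function(start, end, n, what = "interval") {
  if (length(start) != 1L || length(end) != 1L ||
      is.na(start) || is.na(end) || start < 1L || end > n || start > end) {
    stop(sprintf("invalid %s [%s, %s] for sequence of length %d",
                 what, format(start), format(end), n), call. = FALSE)
  }
}
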