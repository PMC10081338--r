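# Shared fixtures and independent oracles for the test suite.

grn <- load_fixture("example_grn")
grn_dcm <- build_dcm(grn)

or_net <- load_fixture("or_gate")

# Independent brute-force prime-implicant enumerator (3^k patterns; k <= 5).
# Never touches the Quine-McCluskey path.
oracle_prime_implicants <- function(lut, k, out) {
  if (k == 0) {
    return(if (lut[1] == out) "" else character(0))
  }
  syms <- c("0", "1", "#")
  grid <- do.call(expand.grid, c(rep(list(syms), k),
                                 stringsAsFactors = FALSE))
  patterns <- apply(as.matrix(grid), 1, paste, collapse = "")
  covers <- function(pat) {
    chars <- strsplit(pat, "")[[1]]
    rows <- 0:(2^k - 1)
    keep <- rep(TRUE, length(rows))
    for (j in seq_len(k)) {
      if (chars[j] == "#") next
      bit <- bitwAnd(bitwShiftR(rows, k - j), 1L)
      keep <- keep & (bit == as.integer(chars[j]))
    }
    rows[keep]
  }
  is_implicant <- vapply(patterns, function(p) {
    r <- covers(p)
    length(r) > 0 && all(lut[r + 1] == out)
  }, logical(1))
  imps <- patterns[is_implicant]
  prime <- vapply(imps, function(p) {
    chars <- strsplit(p, "")[[1]]
    for (j in which(chars != "#")) {
      gen <- chars
      gen[j] <- "#"
      if (paste(gen, collapse = "") %in% imps) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(imps[prime])
}

# Evaluate a node's output on LUT row r via two-symbol schemata; errors if
# the schemata are ambiguous on the row.
eval_via_f2 <- function(f2, row_bits) {
  hits <- vapply(f2, schema_match, logical(1), pc = row_bits)
  outs <- unique(vapply(f2[hits], `[[`, integer(1), "output"))
  expect_length(outs, 1)
  outs
}

row_bits <- function(r, k) {
  vapply(seq_len(k), function(j) bitwAnd(bitwShiftR(r, k - j), 1L), integer(1))
}

# Check a pinning module against the exhaustive-simulation oracle.
module_is_sound <- function(pm, net, pinned) {
  oracle <- brute_force_stabilization(net, pinned)
  all(vapply(pm$module_set, function(su) {
    v <- sub("-[01]$", "", su)
    st <- as.integer(sub("^.*-", "", su))
    v %in% names(oracle) && oracle[[v]] == st
  }, logical(1)))
}

seed_units_of <- function(pm) paste(pm$seed_units, collapse = ",")
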