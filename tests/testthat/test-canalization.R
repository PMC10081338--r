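test_that("prime implicants of the basic gates match the brute-force oracle", {
  # OR gate: one ON input suffices; both inputs must be OFF to stay OFF
  fp <- prime_implicants(or_net$nodes[["x"]])
  expect_setequal(fp$pattern[fp$output == 1], c("1#", "#1"))
  expect_equal(fp$pattern[fp$output == 0], "00")

  # AND gate, expected values frozen from the 3^k enumeration oracle
  and_net <- parse_rules("y* = a and b\na* = a\nb* = b")
  fa <- prime_implicants(and_net$nodes[["y"]])
  expect_equal(fa$pattern[fa$output == 1],
               oracle_prime_implicants(and_net$nodes[["y"]]$lut, 2, 1L))
  expect_equal(fa$pattern[fa$output == 1], "11")
  expect_setequal(fa$pattern[fa$output == 0], c("0#", "#0"))

  # XOR
  xor <- boolean_node("z", c("a", "b"), c(0L, 1L, 1L, 0L))
  fx <- prime_implicants(xor)
  expect_setequal(fx$pattern[fx$output == 1], c("01", "10"))
  expect_setequal(fx$pattern[fx$output == 0], c("00", "11"))

  # constant functions yield a single all-# schema for the realized output
  const <- boolean_node("c", character(0), 1L)
  fc <- prime_implicants(const)
  expect_equal(nrow(fc), 1)
  expect_equal(fc$output, 1L)
  const2 <- boolean_node("c2", c("a", "b"), rep(0L, 4))
  fc2 <- prime_implicants(const2)
  expect_equal(fc2$pattern, "##")
  expect_equal(fc2$output, 0L)
})

test_that("Quine-McCluskey agrees with the enumeration oracle on random LUTs", {
  set.seed(7)
  for (i in 1:40) {
    k <- sample(1:4, 1)
    lut <- sample(0:1, 2^k, replace = TRUE)
    nd <- boolean_node("f", paste0("v", seq_len(k)), lut)
    fp <- prime_implicants(nd)
    for (out in c(0L, 1L)) {
      expect_equal(sort(fp$pattern[fp$output == out]),
                   oracle_prime_implicants(lut, k, out),
                   info = paste("k =", k, "lut =", paste(lut, collapse = "")))
    }
  }
})

test_that("two-symbol regrouping captures input symmetry and is lossless", {
  # OR ON-schemata collapse into one position-free bundle over both inputs
  fp <- prime_implicants(or_net$nodes[["x"]])
  f2 <- two_symbol(fp)
  on <- Filter(function(s) s$output == 1, f2)
  expect_length(on, 1)
  expect_length(on[[1]]$bundles, 1)
  expect_setequal(on[[1]]$bundles[[1]]$positions, c(1, 2))
  expect_setequal(on[[1]]$expansion, c("1#", "#1"))

  # XOR ON-schemata merge into a bundle requiring one ON and one OFF input
  xor <- boolean_node("z", c("a", "b"), c(0L, 1L, 1L, 0L))
  f2x <- two_symbol(prime_implicants(xor))
  onx <- Filter(function(s) s$output == 1, f2x)
  expect_length(onx, 1)
  expect_equal(sort(onx[[1]]$bundles[[1]]$states), c("0", "1"))
  expect_setequal(onx[[1]]$expansion, c("01", "10"))

  # an asymmetric F' stays fixed with no bundles
  asym <- boolean_node("w", c("a", "b"), c(0L, 0L, 1L, 0L))  # a and not b
  f2a <- two_symbol(prime_implicants(asym))
  ona <- Filter(function(s) s$output == 1, f2a)
  expect_length(ona, 1)
  expect_length(ona[[1]]$bundles, 0)
  expect_equal(ona[[1]]$expansion, "10")

  # lossless: flattening F'' reproduces F' exactly, per polarity
  set.seed(11)
  for (i in 1:25) {
    k <- sample(1:5, 1)
    nd <- boolean_node("f", paste0("v", seq_len(k)),
                       sample(0:1, 2^k, replace = TRUE))
    fp <- prime_implicants(nd)
    f2 <- two_symbol(fp)
    for (out in c(0L, 1L)) {
      flat <- as.character(sort(unique(unlist(lapply(
        Filter(function(s) s$output == out, f2), `[[`, "expansion")))))
      expect_equal(flat, sort(fp$pattern[fp$output == out]))
    }
    # no two schemata share an expansion
    keys <- vapply(f2, function(s) {
      paste(s$output, paste(sort(s$expansion), collapse = "|"))
    }, character(1))
    expect_false(anyDuplicated(keys) > 0)
  }
})

test_that("schema matching certifies only guaranteed transitions", {
  expect_true(schema_match("1#", c(1L, NA)))
  expect_false(schema_match("00", c(0L, NA)))  # unknown cannot certify 0
  expect_true(schema_match("00", c(0L, 0L)))
  expect_error(schema_match("00", c(0L, 0L, 1L)), "arity")

  xor <- boolean_node("z", c("a", "b"), c(0L, 1L, 1L, 0L))
  onx <- Filter(function(s) s$output == 1,
                two_symbol(prime_implicants(xor)))[[1]]
  expect_true(schema_match(onx, c(0L, 1L)))
  expect_true(schema_match(onx, c(1L, 0L)))
  expect_false(schema_match(onx, c(1L, NA)))
  expect_false(schema_match(onx, c(1L, 1L)))
  # '#' string form is accepted
  expect_true(schema_match("1#", c("1", "#")))
})

test_that("F, F' and F'' are semantically equivalent on full rows", {
  set.seed(23)
  for (i in 1:30) {
    k <- sample(1:6, 1)
    lut <- sample(0:1, 2^k, replace = TRUE)
    nd <- boolean_node("f", paste0("v", seq_len(k)), lut)
    fp <- prime_implicants(nd)
    f2 <- two_symbol(fp)
    for (r in 0:(2^k - 1)) {
      bits <- row_bits(r, k)
      # exactly the schemata of the correct polarity match (disjointness)
      hits <- vapply(seq_len(nrow(fp)), function(j) {
        schema_match(fp$pattern[j], bits)
      }, logical(1))
      expect_true(all(fp$output[hits] == lut[r + 1]))
      expect_true(any(hits))
      expect_equal(eval_via_f2(f2, bits), lut[r + 1])
    }
  }
})

test_that("F' schemata are prime: adding any wildcard breaks equivalence", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    lut <- sample(0:1, 2^k, replace = TRUE)
    nd <- boolean_node("f", paste0("v", seq_len(k)), lut)
    fp <- prime_implicants(nd)
    for (j in seq_len(nrow(fp))) {
      chars <- strsplit(fp$pattern[j], "")[[1]]
      for (p in which(chars != "#")) {
        gen <- chars
        gen[p] <- "#"
        # the generalized schema must cover a row of the opposite output
        rows <- 0:(2^k - 1)
        keep <- rep(TRUE, 2^k)
        for (q in seq_len(k)) {
          if (gen[q] == "#") next
          keep <- keep & (bitwAnd(bitwShiftR(rows, k - q), 1L) ==
                            as.integer(gen[q]))
        }
        expect_true(any(lut[rows[keep] + 1] != fp$output[j]))
      }
    }
  }
})
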