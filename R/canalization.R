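# Schemata redescription of node logic.
#
# A node's look-up table F is reduced to wildcard schemata F' (prime
# implicants of the ON-set and of the OFF-set; redundant inputs become '#')
# and further to two-symbol schemata F'' in which permutable input
# positions are grouped into position-free bundles.  All prime implicants
# are retained (no minimal-cover step): every canalizing path detectable
# from a partial configuration stays available.

# --- Quine-McCluskey over (bits, mask) implicant pairs ---------------------
# An implicant is a pair of integers: `mask` has a 1 on every fixed
# position, `bits` holds the required values there (0 elsewhere).  Input j
# of k occupies bit (k - j), matching the LUT row order.

qm_prime_implicants <- function(minterms, k) {
  if (length(minterms) == 0) {
    return(data.frame(bits = integer(0), mask = integer(0)))
  }
  if (k == 0) {
    return(data.frame(bits = 0L, mask = 0L))
  }
  full <- 2^k - 1L
  cur <- unique(data.frame(bits = as.integer(minterms), mask = full))
  primes <- list()
  while (nrow(cur) > 0) {
    combined <- rep(FALSE, nrow(cur))
    new_bits <- integer(0)
    new_mask <- integer(0)
    for (mk in unique(cur$mask)) {
      idx <- which(cur$mask == mk)
      v <- cur$bits[idx]
      for (b in which(bitwAnd(bitwShiftR(mk, 0:(k - 1)), 1L) == 1L) - 1L) {
        w <- bitwShiftL(1L, b)
        partner <- bitwXor(v, w)
        hit <- match(partner, v)
        ok <- !is.na(hit)
        if (any(ok)) {
          combined[idx[ok]] <- TRUE
          lower <- bitwAnd(v[ok], bitwNot(w))
          new_bits <- c(new_bits, lower)
          new_mask <- c(new_mask, rep(bitwAnd(mk, bitwNot(w)), sum(ok)))
        }
      }
    }
    if (any(!combined)) {
      primes[[length(primes) + 1]] <- cur[!combined, , drop = FALSE]
    }
    cur <- if (length(new_bits)) {
      unique(data.frame(bits = new_bits, mask = new_mask))
    } else {
      cur[0, , drop = FALSE]
    }
  }
  unique(do.call(rbind, primes))
}

implicant_to_pattern <- function(bits, mask, k) {
  if (k == 0) return("")
  chars <- vapply(seq_len(k), function(j) {
    w <- bitwShiftL(1L, k - j)
    if (bitwAnd(mask, w) == 0L) "#"
    else if (bitwAnd(bits, w) != 0L) "1"
    else "0"
  }, character(1))
  paste(chars, collapse = "")
}

#' Wildcard-schemata redescription (F') of a node
#'
#' Runs Quine-McCluskey minimisation separately on the ON-set and the
#' OFF-set of the node's look-up table and returns all prime implicants of
#' both polarities as wildcard patterns over `{0, 1, #}`.
#'
#' @param node a `boolean_node`.
#' @return a data frame with columns `pattern` (one symbol per ordered
#'   input) and `output` (0/1), sorted deterministically.  A constant
#'   function yields a single all-`#` schema for its realized output only.
#' @export
prime_implicants <- function(node) {
  k <- length(node$inputs)
  res <- list()
  for (out in c(1L, 0L)) {
    rows <- which(node$lut == out) - 1L
    pis <- qm_prime_implicants(rows, k)
    if (nrow(pis)) {
      pats <- vapply(seq_len(nrow(pis)), function(i) {
        implicant_to_pattern(pis$bits[i], pis$mask[i], k)
      }, character(1))
      res[[length(res) + 1]] <- data.frame(pattern = sort(pats, method = "radix"), output = out)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(pattern = character(0), output = integer(0))
  rownames(out) <- NULL
  out
}

# --- Two-symbol schemata ---------------------------------------------------

# All distinct patterns obtained by permuting the symbols of `pattern` at
# `positions` (indices into the pattern string).
permute_positions <- function(pattern, positions) {
  chars <- strsplit(pattern, "")[[1]]
  syms <- chars[positions]
  perms <- unique_perms(syms)
  vapply(perms, function(p) {
    chars[positions] <- p
    paste(chars, collapse = "")
  }, character(1))
}

# Distinct permutations of a symbol multiset (recursive, small inputs).
unique_perms <- function(syms) {
  if (length(syms) <= 1) return(list(syms))
  out <- list()
  for (s in unique(syms)) {
    rest <- syms[-match(s, syms)]
    for (p in unique_perms(rest)) {
      out[[length(out) + 1]] <- c(s, p)
    }
  }
  out
}

two_symbol_schema <- function(k, fixed, bundles, output, expansion) {
  structure(list(k = k, fixed = fixed, bundles = bundles,
                 output = output, expansion = sort(unique(expansion), method = "radix")),
            class = "two_symbol_schema")
}

#' @export
print.two_symbol_schema <- function(x, ...) {
  cat(format_two_symbol(x), "->", x$output, "\n")
  invisible(x)
}

#' Render a two-symbol schema as a pattern string
#'
#' Fixed positions print their symbol, wildcards print `#`, and bundled
#' (position-free) groups print as `(s1,s2,...)°` spans.
#' @param schema a `two_symbol_schema`.
#' @return character scalar.
#' @export
format_two_symbol <- function(schema) {
  if (schema$k == 0) return("()")
  chars <- rep("#", schema$k)
  for (p in names(schema$fixed)) chars[as.integer(p)] <- schema$fixed[[p]]
  extra <- character(0)
  for (b in schema$bundles) {
    chars[b$positions] <- "°"
    extra <- c(extra, paste0("(", paste(b$states, collapse = ","), ")°@",
                             paste(b$positions, collapse = ",")))
  }
  paste0(paste(chars, collapse = ""),
         if (length(extra)) paste0(" ", paste(extra, collapse = " ")) else "")
}

#' Two-symbol redescription (F'') of a set of wildcard schemata
#'
#' Groups wildcard schemata of the same output that are permutations of one
#' another over symmetric input positions into position-free bundles.  The
#' regrouping is lossless: the union of all schema expansions equals the
#' input F' exactly, and no two schemata share an expansion.
#'
#' @param f_prime data frame from [prime_implicants()] (columns `pattern`,
#'   `output`).
#' @param max_k symmetry detection is exhaustive and only attempted for
#'   nodes with at most this many inputs (default 12); beyond it each F'
#'   schema becomes its own pass-through schema with a warning.
#' @return list of `two_symbol_schema` objects.
#' @export
two_symbol <- function(f_prime, max_k = 12L) {
  if (nrow(f_prime) == 0) return(list())
  k <- nchar(f_prime$pattern[1])
  out <- list()
  for (pol in unique(f_prime$output)) {
    pats <- sort(f_prime$pattern[f_prime$output == pol], method = "radix")
    if (k > max_k) {
      warning("two_symbol: k = ", k, " exceeds max_k = ", max_k,
              "; passing wildcard schemata through without symmetry grouping")
      for (p in pats) {
        out[[length(out) + 1]] <- pattern_to_schema(p, pol)
      }
      next
    }
    pool <- pats
    remaining <- pats
    while (length(remaining)) {
      s <- remaining[1]
      groups <- as.list(seq_len(k))
      cur_exp <- s
      repeat {
        merged <- FALSE
        ng <- length(groups)
        for (i in seq_len(max(ng - 1, 0))) {
          for (j in seq(i + 1, ng)) {
            cand_groups <- groups
            cand_groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
            cand_groups <- cand_groups[-j]
            # the full product over all bundles must stay inside F'
            exp <- expansion_of(s, cand_groups)
            if (length(exp) > length(cur_exp) && all(exp %in% pool)) {
              groups <- cand_groups
              cur_exp <- exp
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
        if (!merged) break
      }
      schema <- groups_to_schema(s, groups, pol)
      out[[length(out) + 1]] <- schema
      remaining <- setdiff(remaining, schema$expansion)
    }
  }
  # Deduplicate identical expansions (keep first, deterministic order).
  keys <- vapply(out, function(sc) {
    paste(sc$output, paste(sc$expansion, collapse = "|"))
  }, character(1))
  out[!duplicated(keys)]
}

# Product expansion of a pattern under a position grouping.
expansion_of <- function(pattern, groups) {
  exp <- pattern
  for (g in groups) {
    if (length(g) > 1) {
      exp <- unique(unlist(lapply(exp, permute_positions, positions = g)))
    }
  }
  exp
}

pattern_to_schema <- function(pattern, output) {
  chars <- strsplit(pattern, "")[[1]]
  fixed <- as.list(chars[chars != "#"])
  names(fixed) <- which(chars != "#")
  two_symbol_schema(length(chars), fixed, list(), output, pattern)
}

groups_to_schema <- function(pattern, groups, output) {
  chars <- strsplit(pattern, "")[[1]]
  k <- length(chars)
  fixed <- list()
  bundles <- list()
  for (g in groups) {
    if (length(g) == 1) {
      if (chars[g] != "#") fixed[[as.character(g)]] <- chars[g]
    } else {
      bundles[[length(bundles) + 1]] <-
        list(positions = g, states = sort(chars[g], decreasing = TRUE, method = "radix"))
    }
  }
  expansion <- pattern
  for (b in bundles) {
    expansion <- unique(unlist(lapply(expansion, permute_positions,
                                      positions = b$positions)))
  }
  two_symbol_schema(k, fixed, bundles, output, expansion)
}

#' Number of enputs (essential inputs) of a schema
#'
#' Fixed positions plus non-`#` bundle requirements; this is the t-unit
#' threshold in the canalyzing map.
#' @param schema a `two_symbol_schema`.
#' @return integer.
#' @export
schema_enputs <- function(schema) {
  length(schema$fixed) +
    sum(vapply(schema$bundles, function(b) sum(b$states != "#"), integer(1)))
}

# --- Schema matching -------------------------------------------------------

#' Test whether a partial configuration certifies a schema
#'
#' The known entries of `pc` must guarantee the schema regardless of its
#' unknown (`NA`/`#`) entries: every fixed position is known and equal, and
#' each position-free bundle admits an injective assignment of its non-`#`
#' required states to known matching positions.  An unknown entry never
#' satisfies a required 0/1.
#'
#' @param schema a wildcard pattern string over `{0,1,#}` or a
#'   `two_symbol_schema`.
#' @param pc vector of the node's input states in order; `0`, `1`, or `NA`
#'   (equivalently `"#"`) for unknown.
#' @return logical scalar.
#' @export
schema_match <- function(schema, pc) {
  pc <- normalize_pc(pc)
  if (inherits(schema, "two_symbol_schema")) {
    if (length(pc) != schema$k) {
      stop("arity mismatch: schema has ", schema$k, " inputs, pc has ",
           length(pc))
    }
    for (p in names(schema$fixed)) {
      v <- pc[as.integer(p)]
      if (is.na(v) || v != as.integer(schema$fixed[[p]])) return(FALSE)
    }
    for (b in schema$bundles) {
      vals <- pc[b$positions]
      r1 <- sum(b$states == "1")
      r0 <- sum(b$states == "0")
      c1 <- sum(!is.na(vals) & vals == 1L)
      c0 <- sum(!is.na(vals) & vals == 0L)
      if (c1 < r1 || c0 < r0) return(FALSE)
    }
    return(TRUE)
  }
  chars <- strsplit(schema, "")[[1]]
  if (length(pc) != length(chars)) {
    stop("arity mismatch: schema has ", length(chars), " symbols, pc has ",
         length(pc))
  }
  for (j in seq_along(chars)) {
    if (chars[j] == "#") next
    if (is.na(pc[j]) || pc[j] != as.integer(chars[j])) return(FALSE)
  }
  TRUE
}

normalize_pc <- function(pc) {
  if (is.character(pc)) {
    pc <- suppressWarnings(ifelse(pc == "#", NA_integer_, as.integer(pc)))
  }
  as.integer(pc)
}

# Evaluate a node via its wildcard schemata on a full input row; used by the
# semantic-equivalence property tests.
eval_via_fprime <- function(f_prime, row_bits) {
  hits <- vapply(seq_len(nrow(f_prime)), function(i) {
    schema_match(f_prime$pattern[i], row_bits)
  }, logical(1))
  outs <- unique(f_prime$output[hits])
  if (length(outs) != 1) {
    stop("wildcard schemata are not a function on this row")
  }
  outs
}
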