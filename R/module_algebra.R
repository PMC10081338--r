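# Interactions between pathway modules and the module hierarchy.
#
# Two modules interact through the unfolding of the union of their seed
# sets.  Synergy (extra s-units fire), logical obstruction (s-units are
# suppressed), subsumption and decoupling follow by set algebra on the
# module sets; complex modules are maximal modules whose every seed-set
# bipartition is synergistic, and core complex modules additionally have
# every single seed generate a maximal s = 1 module.

#' Classify the interaction between two pathway modules
#'
#' Both modules must have been unfolded in the same perturbation mode.  The
#' union of their seed sets is unfolded and the set-difference tests
#' applied: synergy when the combination fires s-units absent from the
#' union of the separate unfoldings, logical obstruction when s-units of
#' the separate unfoldings fail to fire in the combination, decoupled when
#' there is no overlap, obstruction, or synergy.  A contradictory seed
#' union (a variable seeded in both states) is reported as
#' obstruction-by-seed-contradiction without unfolding.
#'
#' @param mi,mj `pathway_module` objects.
#' @param dcm the DCM both were unfolded on.
#' @return list with logical flags `subsumed` (mi by mj), `subsumes`,
#'   `partially_subsumed`, `temporally_subsumed` (with shift `k`),
#'   `submodule`, `obstruction`, `synergy`, `decoupled`,
#'   `seed_contradiction`, witnesses, and the combined module (if defined).
#' @export
classify_interaction <- function(mi, mj, dcm) {
  if (mi$mode != mj$mode) stop("modules were unfolded in different modes")
  Si <- mi$module_set
  Sj <- mj$module_set
  overlap <- intersect(Si, Sj)
  subsumed <- all(Si %in% Sj)
  subsumes <- all(Sj %in% Si)
  ts <- temporal_subsumption(mi, mj)

  union_spec <- rbind(mi$seeds, mj$seeds)
  union_spec <- union_spec[!duplicated(union_spec[c("variable", "state")]), ,
                           drop = FALSE]
  contradiction <- anyDuplicated(union_spec$variable) > 0

  if (contradiction) {
    return(list(
      subsumed = subsumed, subsumes = subsumes,
      partially_subsumed = length(overlap) > 0 && !subsumed && !subsumes,
      temporally_subsumed = ts$subsumed, k = ts$k,
      submodule = is_submodule(mi, mj),
      obstruction = TRUE, obstruction_witness = character(0),
      synergy = FALSE, synergy_witness = character(0),
      decoupled = FALSE, seed_contradiction = TRUE, combined = NULL))
  }
  mij <- unfold(dcm, union_spec)
  Sij <- mij$module_set
  sep <- union(Si, Sj)
  synergy_witness <- setdiff(Sij, sep)
  obstruction_witness <- setdiff(sep, Sij)
  list(
    subsumed = subsumed, subsumes = subsumes,
    partially_subsumed = length(overlap) > 0 && !subsumed && !subsumes,
    temporally_subsumed = ts$subsumed, k = ts$k,
    submodule = is_submodule(mi, mj),
    obstruction = length(obstruction_witness) > 0,
    obstruction_witness = obstruction_witness,
    synergy = length(synergy_witness) > 0,
    synergy_witness = synergy_witness,
    decoupled = length(overlap) == 0 && length(synergy_witness) == 0 &&
      length(obstruction_witness) == 0,
    seed_contradiction = FALSE,
    combined = mij)
}

# Mi temporally subsumed by Mj: exists shift k >= 0 with slice-wise
# containment of both s- and t-sets.
temporal_subsumption <- function(mi, mj) {
  ni <- length(mi$slices)
  nj <- length(mj$slices)
  for (k in 0:max(nj - ni, 0)) {
    if (k + ni > nj) break
    ok <- all(vapply(seq_len(ni), function(t) {
      a <- mi$slices[[t]]
      b <- mj$slices[[t + k]]
      all(a$s_fired %in% b$s_fired) && all(a$t_fired %in% b$t_fired)
    }, logical(1)))
    if (ok) return(list(subsumed = TRUE, k = k))
  }
  list(subsumed = FALSE, k = NA_integer_)
}

is_submodule <- function(mi, mj) {
  length(mi$seed_units) > 0 &&
    all(mi$seed_units %in% mj$seed_units) &&
    length(mi$seed_units) < length(mj$seed_units)
}

# ---------------------------------------------------------------------------
# Enumeration

#' Enumerate all pathway modules of a given seed-set size
#'
#' One module per consistent seed set of size `s` (no variable in both
#' states), giving `2^s * choose(n, s)` modules.
#'
#' @param dcm a `dcm`.
#' @param s seed-set size.
#' @param mode perturbation mode applied to every seed.
#' @param cap maximum number of seed sets to unfold (default 10^6).
#' @return list of `pathway_module` objects.
#' @export
enumerate_pathway_modules <- function(dcm, s, mode = "pinning", cap = 1e6) {
  vars <- node_names(dcm$net)
  n <- length(vars)
  if (s < 1 || s > n) stop("s must be in 1..n")
  count <- 2^s * choose(n, s)
  if (count > cap) {
    stop("seed-set enumeration would produce ", count,
         " modules, exceeding cap = ", cap)
  }
  combos <- utils::combn(vars, s, simplify = FALSE)
  states <- as.matrix(expand.grid(rep(list(c(0L, 1L)), s)))
  out <- vector("list", length(combos) * nrow(states))
  i <- 0L
  for (vs in combos) {
    for (r in seq_len(nrow(states))) {
      st <- states[r, ]
      names(st) <- vs
      i <- i + 1L
      out[[i]] <- unfold(dcm, seed_spec(st, mode = mode))
    }
  }
  out
}

module_set_key <- function(pm) paste(pm$module_set, collapse = "|")
seed_key <- function(pm) paste(pm$seed_units, collapse = "|")

#' Maximal pathway modules at a given seed-set size
#'
#' A module of seed size `s` is maximal when its module set is not a proper
#' subset of the module set of any module with seed size at most `s`
#' (the pinning containment test); modules with identical sets are both retained.
#'
#' @param modules_by_s list of module lists, element `x` holding all
#'   modules of seed size `x`, for `x = 1..s` (from
#'   [enumerate_pathway_modules()]).
#' @param s seed-set size whose maximal set is requested.
#' @return list of maximal `pathway_module`s of seed size `s`.
#' @export
maximal_modules <- function(modules_by_s, s) {
  cand <- modules_by_s[[s]]
  all_small <- unlist(modules_by_s[seq_len(s)], recursive = FALSE)
  sets <- lapply(all_small, `[[`, "module_set")
  keep <- vapply(cand, function(mi) {
    Si <- mi$module_set
    for (j in seq_along(all_small)) {
      Sj <- sets[[j]]
      if (length(Si) < length(Sj) && all(Si %in% Sj)) return(FALSE)
    }
    TRUE
  }, logical(1))
  cand[keep]
}

#' Complex pathway modules at a given seed-set size
#'
#' Maximal modules for which every nonempty bipartition of the seed set is
#' synergistic: the joint unfolding fires s-units beyond the union of the
#' two parts' unfoldings.  At `s = 1` every maximal module is complex.
#'
#' @param dcm a `dcm`.
#' @param s seed-set size (capped; bipartition checking is exponential in s).
#' @param mode perturbation mode.
#' @param modules_by_s optional precomputed enumeration for sizes `1..s`.
#' @param s_cap largest allowed `s` (default 6).
#' @return list of complex `pathway_module`s of seed size `s`.
#' @export
complex_modules <- function(dcm, s, mode = "pinning", modules_by_s = NULL,
                            s_cap = 6L) {
  if (s > s_cap) stop("s = ", s, " exceeds the bipartition cap ", s_cap)
  if (is.null(modules_by_s)) {
    modules_by_s <- lapply(seq_len(s), function(x) {
      enumerate_pathway_modules(dcm, x, mode = mode)
    })
  }
  lam <- maximal_modules(modules_by_s, s)
  if (s == 1) return(lam)
  # memoized unfolding by seed-unit key over smaller seed sets
  memo <- new.env(parent = emptyenv())
  for (x in seq_len(s - 1)) {
    for (pm in modules_by_s[[x]]) assign(seed_key(pm), pm, envir = memo)
  }
  keep <- vapply(lam, function(mi) {
    seeds <- mi$seed_units
    idx <- seq_along(seeds)
    for (sz in seq_len(floor(s / 2))) {
      for (part in utils::combn(idx, sz, simplify = FALSE)) {
        if (sz == s - sz && part[1] != 1) next  # unordered bipartitions
        a <- sort(seeds[part], method = "radix")
        b <- sort(seeds[-part], method = "radix")
        ma <- get(paste(a, collapse = "|"), envir = memo)
        mb <- get(paste(b, collapse = "|"), envir = memo)
        synergy <- length(setdiff(mi$module_set,
                                  union(ma$module_set, mb$module_set))) > 0
        if (!synergy) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  lam[keep]
}

#' Core filter: the maximal seed heuristic
#'
#' Retains complex modules all of whose single seeds generate maximal
#' `s = 1` pathway modules.
#'
#' @param i_s list of complex `pathway_module`s.
#' @param lambda_1 the maximal modules at `s = 1` (list of modules).
#' @return the core complex modules among `i_s`.
#' @export
core_filter <- function(i_s, lambda_1) {
  core_seeds <- vapply(lambda_1, function(pm) pm$seed_units, character(1))
  keep <- vapply(i_s, function(pm) all(pm$seed_units %in% core_seeds),
                 logical(1))
  i_s[keep]
}

#' Build the full module catalog of a DCM
#'
#' Enumerates all pathway modules for seed sizes `1..s_max`, then the
#' maximal, complex, and core complex modules per size.
#'
#' @param dcm a `dcm`.
#' @param s_max maximum seed-set size (capped at 6 by default through
#'   [complex_modules()]).
#' @param mode perturbation mode (the module hierarchy defaults to pinning).
#' @param cap enumeration cap passed to [enumerate_pathway_modules()].
#' @return object of class `module_catalog` with per-size lists `all`,
#'   `maximal`, `complex`, `core`, and `counts`.
#' @export
module_catalog <- function(dcm, s_max = 2L, mode = "pinning", cap = 1e6) {
  modules_by_s <- lapply(seq_len(s_max), function(x) {
    enumerate_pathway_modules(dcm, x, mode = mode, cap = cap)
  })
  maximal <- lapply(seq_len(s_max), function(x) {
    maximal_modules(modules_by_s, x)
  })
  complex <- lapply(seq_len(s_max), function(x) {
    if (x == 1) maximal[[1]]
    else complex_modules(dcm, x, mode = mode, modules_by_s = modules_by_s)
  })
  core <- lapply(seq_len(s_max), function(x) {
    core_filter(complex[[x]], maximal[[1]])
  })
  counts <- data.frame(
    s = seq_len(s_max),
    pathway = vapply(modules_by_s, length, integer(1)),
    maximal = vapply(maximal, length, integer(1)),
    complex = vapply(complex, length, integer(1)),
    core = vapply(core, length, integer(1)))
  structure(list(all = modules_by_s, maximal = maximal, complex = complex,
                 core = core, counts = counts, mode = mode, dcm = dcm),
            class = "module_catalog")
}

#' @export
print.module_catalog <- function(x, ...) {
  cat("Module catalog (", x$mode, " perturbation)\n", sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Candidate pool of a catalog for cover optimisation
#'
#' Core complex modules (or all complex modules) with seed size at most
#' `s`, deduplicated by module set keeping the lexicographically smallest
#' seed set.
#'
#' @param catalog a `module_catalog`.
#' @param s maximum seed-set size.
#' @param core use core complex modules (default) or all complex modules.
#' @return list of `pathway_module`s.
#' @export
catalog_pool <- function(catalog, s = length(catalog$complex), core = TRUE) {
  src <- if (core) catalog$core else catalog$complex
  pool <- unlist(src[seq_len(min(s, length(src)))], recursive = FALSE)
  ord <- order(vapply(pool, seed_key, character(1)), method = "radix")
  pool <- pool[ord]
  keys <- vapply(pool, module_set_key, character(1))
  pool[!duplicated(keys)]
}
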