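# Covers of the DCM and the mean dynamical modularity statistic.
#
# A cover is a set of pathway modules whose module sets jointly contain all
# 2n s-units.  The independence of a module within a cover is the fraction
# of its s-units held by no other member; the mean of these scores is the
# mean dynamical modularity D-bar.  The optimal cover maximizes D-bar over
# full covers drawn from the complex modules with seed size <= s (an
# NP-hard set-cover variant, solved exactly by branch and bound at desk
# scale and estimated by greedy selection otherwise).

#' Round half away from zero
#'
#' Decimal rounding as printed results round (0.825 -> 0.83 at two
#' digits), unlike [round()]'s round-half-to-even on binary doubles.
#' @param x numeric vector.
#' @param digits decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Independence of a module from a set of modules
#'
#' `|S_i - S_Sigma| / |S_i|` where `S_Sigma` is the union of the module
#' sets in `sigma`.
#'
#' @param mi a `pathway_module`.
#' @param sigma list of `pathway_module`s (may be empty).
#' @return numeric score in `[0, 1]`.
#' @export
independence <- function(mi, sigma) {
  Si <- mi$module_set
  if (length(Si) == 0) stop("independence is undefined for an empty module set")
  SS <- unique(unlist(lapply(sigma, `[[`, "module_set")))
  length(setdiff(Si, SS)) / length(Si)
}

#' Assemble a cover object
#'
#' @param modules list of `pathway_module`s.
#' @param all_sunits character vector of the DCM's 2n s-units.
#' @return object of class `dcm_cover` with the union set and coverage flag.
#' @export
dcm_cover <- function(modules, all_sunits) {
  union_set <- unique(unlist(lapply(modules, `[[`, "module_set")))
  structure(list(modules = modules, union_set = union_set,
                 is_full = setequal(union_set, all_sunits) &&
                   all(all_sunits %in% union_set),
                 uncovered = setdiff(all_sunits, union_set),
                 size = length(modules)),
            class = "dcm_cover")
}

#' @export
print.dcm_cover <- function(x, ...) {
  cat("Cover of ", x$size, " modules (",
      if (x$is_full) "full" else paste0("misses ",
                                        length(x$uncovered), " s-units"),
      ")\n", sep = "")
  for (m in x$modules) {
    cat("  M(", paste(m$seed_units, collapse = ","), ")  |S| = ",
        length(m$module_set), "\n", sep = "")
  }
  invisible(x)
}

#' Mean dynamical modularity of a cover
#'
#' Per-module independence from the rest of the cover and the arithmetic
#' mean of the scores.
#'
#' @param cover a `dcm_cover` or a plain list of `pathway_module`s.
#' @return object of class `modularity_report` with `scores` (named by seed
#'   sets), `mean`, and the cover.
#' @export
mean_dynamical_modularity <- function(cover) {
  modules <- if (inherits(cover, "dcm_cover")) cover$modules else cover
  if (length(modules) == 0) stop("cannot score an empty cover")
  scores <- vapply(seq_along(modules), function(i) {
    independence(modules[[i]], modules[-i])
  }, numeric(1))
  names(scores) <- vapply(modules, function(m) {
    paste(m$seed_units, collapse = ",")
  }, character(1))
  structure(list(scores = scores, mean = mean(scores), cover = cover),
            class = "modularity_report")
}

#' @export
print.modularity_report <- function(x, ...) {
  cat("Mean dynamical modularity: ", round(x$mean, 4), "\n", sep = "")
  for (nm in names(x$scores)) {
    cat(sprintf("  ind M(%s) = %.4f\n", nm, x$scores[[nm]]))
  }
  invisible(x)
}

cover_mean <- function(sets) {
  mean(vapply(seq_along(sets), function(i) {
    Si <- sets[[i]]
    length(setdiff(Si, unique(unlist(sets[-i])))) / length(Si)
  }, numeric(1)))
}

#' Exact optimal cover by branch and bound
#'
#' Depth-first search over subsets of the candidate pool (complex modules
#' with seed size at most `s`), pruning branches that cannot complete a
#' full cover within `q` modules or cannot beat the best mean dynamical
#' modularity found so far.  Also reports a minimum-cardinality cover
#' (ties broken by higher D-bar, then lexicographic seed sets).
#'
#' @param pool list of candidate `pathway_module`s (see [catalog_pool()]).
#' @param all_sunits the DCM's s-units.
#' @param q maximum cover size (default unlimited).
#' @return list with `cover` (a `dcm_cover`), `report`
#'   (a `modularity_report`), `minimal_cover`, `minimal_report`, and
#'   `solver = "exact"`; errors when the pool cannot cover the DCM,
#'   reporting the uncoverable s-units.
#' @export
optimal_cover_exact <- function(pool, all_sunits, q = Inf) {
  if (length(pool) == 0) stop("empty candidate pool")
  sets <- lapply(pool, `[[`, "module_set")
  pool_union <- unique(unlist(sets))
  uncoverable <- setdiff(all_sunits, pool_union)
  if (length(uncoverable)) {
    stop("candidate pool cannot cover the DCM; uncoverable s-units: ",
         paste(uncoverable, collapse = ", "))
  }
  ord <- order(-vapply(sets, length, integer(1)),
               vapply(pool, seed_key, character(1)), method = "radix")
  pool <- pool[ord]
  sets <- sets[ord]
  np <- length(pool)
  # suffix unions for coverage pruning
  suffix <- vector("list", np + 1)
  suffix[[np + 1]] <- character(0)
  for (i in np:1) suffix[[i]] <- union(sets[[i]], suffix[[i + 1]])

  best <- list(mean = -Inf, idx = NULL)
  best_min <- list(size = Inf, mean = -Inf, idx = NULL)

  consider <- function(idx) {
    m <- cover_mean(sets[idx])
    if (m > best$mean + 1e-12) best <<- list(mean = m, idx = idx)
    sz <- length(idx)
    if (sz < best_min$size ||
        (sz == best_min$size && m > best_min$mean + 1e-12)) {
      best_min <<- list(size = sz, mean = m, idx = idx)
    }
  }

  dfs <- function(i, idx, covered) {
    if (setequal(covered, all_sunits)) consider(idx)
    if (i > np || length(idx) >= q) return()
    missing <- setdiff(all_sunits, covered)
    if (!all(missing %in% suffix[[i]])) return()
    # Upper bound on the attainable mean: chosen modules can only lose
    # independence as the cover grows; the remaining slots score at most 1.
    if (length(idx) > 0 && is.finite(best$mean)) {
      cur <- vapply(seq_along(idx), function(jj) {
        Si <- sets[[idx[jj]]]
        length(setdiff(Si, unique(unlist(sets[idx[-jj]])))) / length(Si)
      }, numeric(1))
      depth <- length(idx)
      hi <- max(vapply(depth:min(np, q), function(m) {
        (sum(cur) + (m - depth)) / m
      }, numeric(1)))
      if (hi <= best$mean + 1e-12) return()
    }
    dfs(i + 1, c(idx, i), union(covered, sets[[i]]))
    dfs(i + 1, idx, covered)
  }
  dfs(1, integer(0), character(0))

  if (is.null(best$idx)) {
    stop("no full cover of size <= ", q, " exists over the candidate pool")
  }
  cov <- dcm_cover(pool[best$idx], all_sunits)
  mincov <- dcm_cover(pool[best_min$idx], all_sunits)
  list(cover = cov, report = mean_dynamical_modularity(cov),
       minimal_cover = mincov,
       minimal_report = mean_dynamical_modularity(mincov),
       solver = "exact")
}

#' Greedy cover estimation
#'
#' Starts from an empty selection and iteratively adds the candidate with
#' the highest independence from the current selection (ties: larger
#' module set, then smaller seed set, then lexicographic seed names) until
#' the DCM is covered or `q` selections have been made.  The resulting
#' D-bar is a lower bound on the exact optimum.
#'
#' @param pool list of candidate `pathway_module`s.
#' @param all_sunits the DCM's s-units.
#' @param q optional early stop on the number of selections.
#' @return list with `cover`, `report`, `solver = "greedy"`.
#' @export
greedy_cover <- function(pool, all_sunits, q = Inf) {
  if (length(pool) == 0) stop("empty candidate pool")
  sets <- lapply(pool, `[[`, "module_set")
  uncoverable <- setdiff(all_sunits, unique(unlist(sets)))
  if (length(uncoverable)) {
    stop("candidate pool cannot cover the DCM; uncoverable s-units: ",
         paste(uncoverable, collapse = ", "))
  }
  chosen <- integer(0)
  covered <- character(0)
  while (!all(all_sunits %in% covered) && length(chosen) < q) {
    rem <- setdiff(seq_along(pool), chosen)
    ind <- vapply(rem, function(i) {
      length(setdiff(sets[[i]], covered)) / length(sets[[i]])
    }, numeric(1))
    size <- vapply(rem, function(i) length(sets[[i]]), integer(1))
    nseeds <- vapply(rem, function(i) length(pool[[i]]$seed_units), integer(1))
    keys <- vapply(rem, function(i) seed_key(pool[[i]]), character(1))
    o <- order(-ind, -size, nseeds, keys, method = "radix")
    pick <- rem[o[1]]
    chosen <- c(chosen, pick)
    covered <- union(covered, sets[[pick]])
  }
  cov <- dcm_cover(pool[chosen], all_sunits)
  list(cover = cov, report = mean_dynamical_modularity(cov),
       solver = "greedy")
}

#' Modularity curve and characteristic seed number
#'
#' Computes the optimal-cover mean dynamical modularity for maximum seed
#' sizes `s = 1..s_max` and returns the smallest `s` at which the curve
#' stops increasing (plateau onset).
#'
#' @param dcm a `dcm`.
#' @param s_max largest maximum seed size to examine.
#' @param solver `"exact"` or `"greedy"`.
#' @param core restrict candidate pools to core complex modules (default).
#' @param q maximum cover size per search.
#' @param eps plateau tolerance on the D-bar increase (default 1e-9).
#' @param catalog optional precomputed [module_catalog()] of depth `s_max`.
#' @return list with `s_star`, `curve` (data frame of s, D-bar, cover
#'   size), `plateau_found`, and the per-s cover results.
#' @export
characteristic_seed_number <- function(dcm, s_max = 3L,
                                       solver = c("exact", "greedy"),
                                       core = TRUE, q = Inf, eps = 1e-9,
                                       catalog = NULL) {
  solver <- match.arg(solver)
  if (is.null(catalog)) catalog <- module_catalog(dcm, s_max = s_max)
  results <- vector("list", s_max)
  dbar <- numeric(s_max)
  csize <- integer(s_max)
  for (s in seq_len(s_max)) {
    pool <- catalog_pool(catalog, s = s, core = core)
    res <- if (solver == "exact") {
      optimal_cover_exact(pool, dcm$s_units, q = q)
    } else {
      greedy_cover(pool, dcm$s_units, q = q)
    }
    results[[s]] <- res
    dbar[s] <- res$report$mean
    csize[s] <- res$cover$size
  }
  s_star <- NA_integer_
  plateau <- FALSE
  for (s in seq_len(s_max - 1)) {
    if (dbar[s + 1] - dbar[s] <= eps) {
      s_star <- s
      plateau <- TRUE
      break
    }
  }
  if (!plateau) s_star <- s_max
  list(s_star = s_star, plateau_found = plateau,
       curve = data.frame(s = seq_len(s_max), dbar = dbar,
                          cover_size = csize),
       covers = results, solver = solver)
}
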