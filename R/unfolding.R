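# Dynamical unfolding of pathway modules.
#
# Seeds fire at t = 0.  At each step the firing partial configuration is
# built from the s-units firing at t; a t-unit fires at t when its schema
# is certified by that configuration (dt = 0), and its target s-unit fires
# at t + 1 (dt = 1).  Pinned seeds fire at every step and block their
# opposite s-unit forever; pulsed seeds fire only at t = 0.  Under pure
# pinning the fired set grows monotonically (first-fired state wins) and
# unfolding ends at a fixpoint; under pulse or mixed perturbation it ends
# when a slice repeats (limit cycle) or is empty.

#' Parse a seed specification
#'
#' Seeds may be given as strings `"var-state"` (e.g. `"P1-1"`), optionally
#' with a per-seed mode suffix `":pin"` / `":pulse"` (e.g. `"P1-1:pulse"`),
#' or as a named 0/1 vector.  Seeds without a suffix take `mode`.
#'
#' @param seeds character vector or named 0/1 vector.
#' @param mode default perturbation mode, `"pinning"` or `"pulse"`.
#' @return data frame with columns `variable`, `state`, `mode`.
#' @export
seed_spec <- function(seeds, mode = c("pinning", "pulse")) {
  mode <- match.arg(mode)
  if (!is.null(names(seeds)) && any(nzchar(names(seeds)))) {
    df <- data.frame(variable = names(seeds), state = as.integer(seeds),
                     mode = mode, stringsAsFactors = FALSE)
  } else {
    parts <- regmatches(seeds,
                        regexec("^(.*)-([01])(?::(pin|pinning|pulse))?$",
                                as.character(seeds), perl = TRUE))
    bad <- vapply(parts, length, integer(1)) < 4
    if (any(bad)) {
      stop("unparseable seed(s): ", paste(seeds[bad], collapse = ", "))
    }
    df <- data.frame(
      variable = vapply(parts, `[[`, character(1), 2),
      state = as.integer(vapply(parts, `[[`, character(1), 3)),
      mode = vapply(parts, function(p) {
        m <- p[[4]]
        if (!nzchar(m)) mode else if (m == "pulse") "pulse" else "pinning"
      }, character(1)),
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(df$variable)) {
    dup <- df$variable[duplicated(df$variable)]
    both <- vapply(unique(dup), function(v) {
      length(unique(df$state[df$variable == v])) > 1
    }, logical(1))
    if (any(both)) {
      stop("contradictory seed set: variable(s) ",
           paste(unique(dup)[both], collapse = ", "), " seeded in both states")
    }
    df <- df[!duplicated(df$variable), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

slice_key <- function(s_fired) paste(sort(s_fired, method = "radix"), collapse = "|")

#' Unfold a pathway module from a seed set
#'
#' @param dcm a [build_dcm()] object.
#' @param seeds seed specification (see [seed_spec()]).
#' @param mode default perturbation mode for seeds without a per-seed mode.
#' @param max_steps safety cap on the number of slices (default `20 n`);
#'   exceeding it signals a bookkeeping bug since unfolding must terminate.
#' @return object of class `pathway_module`: seed data frame, `slices`
#'   (each with `t`, `s_fired`, `t_fired`), `module_set` (all s-units that
#'   ever fire), `first_fire` times, `length` (T), and `termination`
#'   (`"fixpoint"`, `"repeat"`, or `"empty"`; `period` for limit cycles).
#' @export
unfold <- function(dcm, seeds, mode = c("pinning", "pulse"),
                   max_steps = NULL) {
  mode <- match.arg(mode)
  spec <- if (is.data.frame(seeds)) seeds else seed_spec(seeds, mode)
  net <- dcm$net
  vars <- node_names(net)
  unknown <- setdiff(spec$variable, vars)
  if (length(unknown)) {
    stop("seed variable(s) not in network: ", paste(unknown, collapse = ", "))
  }
  n <- length(vars)
  if (is.null(max_steps)) max_steps <- 10L * 2L * n
  seed_units <- sunit(spec$variable, spec$state)
  pinned_units <- seed_units[spec$mode == "pinning"]
  pinned_blocked <- sunit_opposite(pinned_units)
  pure_pinning <- all(spec$mode == "pinning")

  S <- sort(seed_units, method = "radix")
  fired_ever <- character(0)
  first_fire <- integer(0)
  slices <- list()
  seen <- character(0)
  t <- 0L
  termination <- NULL
  period <- NA_integer_

  repeat {
    pc <- rep(NA_integer_, n)
    names(pc) <- vars
    if (length(S)) pc[sunit_variable(S)] <- sunit_state(S)
    theta <- names(dcm$t_units)[vapply(dcm$t_units, tunit_matches,
                                       logical(1), pc_global = pc, net = net)]
    slices[[t + 1L]] <- list(t = t, s_fired = S, t_fired = theta)
    seen[t + 1L] <- slice_key(S)
    new_first <- setdiff(S, names(first_fire))
    first_fire[new_first] <- t
    fired_ever <- union(fired_ever, S)

    targets <- unique(vapply(dcm$t_units[theta], `[[`, character(1), "target"))
    targets <- setdiff(targets, pinned_blocked)
    if (pure_pinning) {
      # first-fired state wins: a derived s-unit whose opposite already
      # fired stays blocked (cannot arise from consistent schemata, but
      # asserted)
      opp_seen <- targets[sunit_opposite(targets) %in% fired_ever]
      if (length(opp_seen)) {
        stop("contradictory derivation under pinning for: ",
             paste(opp_seen, collapse = ", "))
      }
      S_next <- sort(union(union(S, targets), pinned_units), method = "radix")
    } else {
      S_next <- sort(union(targets, pinned_units), method = "radix")
      both <- intersect(S_next, sunit_opposite(S_next))
      if (length(both)) {
        stop("within-slice contradiction for: ", paste(both, collapse = ", "))
      }
    }

    if (length(S_next) == 0) {
      t <- t + 1L
      slices[[t + 1L]] <- list(t = t, s_fired = character(0),
                               t_fired = character(0))
      termination <- "empty"
      break
    }
    hit <- match(slice_key(S_next), seen)
    if (!is.na(hit)) {
      termination <- if (hit == t + 1L) "fixpoint" else "repeat"
      if (termination == "repeat") period <- t + 2L - hit
      break
    }
    S <- S_next
    t <- t + 1L
    if (t > max_steps) {
      stop("unfolding exceeded max_steps = ", max_steps,
           "; this indicates a bookkeeping bug")
    }
  }

  module_set <- sort(names(first_fire), method = "radix")
  structure(list(seeds = spec, seed_units = sort(seed_units, method = "radix"),
                 mode = if (pure_pinning) "pinning"
                        else if (all(spec$mode == "pulse")) "pulse"
                        else "mixed",
                 slices = slices,
                 module_set = module_set,
                 first_fire = first_fire[module_set],
                 length = t,
                 termination = termination,
                 period = period),
            class = "pathway_module")
}

#' @export
print.pathway_module <- function(x, ...) {
  cat("Pathway module M(", paste(x$seed_units, collapse = ", "), ") [",
      x$mode, "]\n", sep = "")
  cat("  size ", length(x$module_set), ", length ", x$length,
      ", termination: ", x$termination,
      if (!is.na(x$period)) paste0(" (period ", x$period, ")") else "",
      "\n", sep = "")
  cat("  module set: ", paste(x$module_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Size of a pathway module
#' @param pm a `pathway_module`.
#' @return `|S|`, the number of s-units that ever fire (seeds included).
#' @export
module_size <- function(pm) length(pm$module_set)

#' Length of a pathway module
#' @param pm a `pathway_module`.
#' @return T, the index of the last slice of the unfolding.
#' @export
module_length <- function(pm) pm$length

#' Does a pinning module resolve an attractor?
#'
#' TRUE when the module set assigns a state to every network variable; the
#' implied full configuration is then verified to be a fixed point of the
#' synchronous dynamics.
#'
#' @param pm a pinning-mode `pathway_module`.
#' @param net the underlying `boolean_network`.
#' @return logical scalar.
#' @export
is_attractor_resolving <- function(pm, net) {
  if (pm$mode != "pinning") stop("attractor resolution is defined for pinning modules")
  vars <- node_names(net)
  if (length(pm$module_set) < length(vars)) return(FALSE)
  config <- sunit_state(pm$module_set)
  names(config) <- sunit_variable(pm$module_set)
  if (!setequal(names(config), vars)) return(FALSE)
  nxt <- synchronous_step(net, config[vars])
  if (!identical(unname(nxt[vars]), unname(config[vars]))) {
    stop("module set covers all variables but is not a fixed point; ",
         "inconsistent unfolding")
  }
  TRUE
}

#' Timeline matrix of a module's unfolding
#'
#' Rows are variables, columns are time steps `t0..tT`; cells are `"0"`,
#' `"1"`, or `"#"` for unknown, reproducing the tabular unfolding view.
#'
#' @param pm a `pathway_module`.
#' @param net optional network giving the row order (defaults to the
#'   variables appearing in the module).
#' @return character matrix.
#' @export
module_timeline <- function(pm, net = NULL) {
  vars <- if (!is.null(net)) node_names(net) else
    unique(sunit_variable(pm$module_set))
  mat <- matrix("#", nrow = length(vars), ncol = length(pm$slices),
                dimnames = list(vars,
                                paste0("t", vapply(pm$slices, `[[`,
                                                   integer(1), "t"))))
  for (sl in pm$slices) {
    if (!length(sl$s_fired)) next
    mat[sunit_variable(sl$s_fired), sl$t + 1L] <-
      as.character(sunit_state(sl$s_fired))
  }
  mat
}
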