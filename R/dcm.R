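# The dynamics canalization map (DCM).
#
# The DCM is a threshold network with one s-unit per (variable, state) pair
# (2n in total for a Boolean network) and one t-unit per two-symbol schema
# of every node.  A t-unit has threshold tau equal to its schema's enput
# count and fires when it receives tau simultaneous signals; fibres from
# s-units to t-units carry signals instantly (dt = 0) while a firing t-unit
# raises its target s-unit one step later (dt = 1).  Canonical firing
# semantics are schema matching on the current partial configuration; the
# threshold/fibre representation is maintained for structure and export and
# is asserted equivalent by the test suite.

sunit <- function(variable, state) paste0(variable, "-", state)

sunit_variable <- function(s) sub("-[01]$", "", s)
sunit_state <- function(s) as.integer(sub("^.*-", "", s))
sunit_opposite <- function(s) {
  paste0(sunit_variable(s), "-", 1L - sunit_state(s))
}

#' All s-units of a network
#' @param net a `boolean_network`.
#' @return character vector of `var-0` / `var-1` names, length `2n`.
#' @export
s_units <- function(net) {
  vars <- node_names(net)
  as.vector(rbind(paste0(vars, "-0"), paste0(vars, "-1")))
}

# Build the t-units of one node's canalyzing map from its F''.
make_tunits <- function(node, f2) {
  lapply(seq_along(f2), function(i) {
    sc <- f2[[i]]
    fibres <- list()
    for (p in names(sc$fixed)) {
      pos <- as.integer(p)
      fibres[[length(fibres) + 1]] <- list(
        sources = sunit(node$inputs[pos], as.integer(sc$fixed[[p]])),
        m = 1L)
    }
    for (b in sc$bundles) {
      req <- b$states[b$states != "#"]
      src <- unlist(lapply(unique(req), function(st) {
        sunit(node$inputs[b$positions], as.integer(st))
      }))
      fibres[[length(fibres) + 1]] <- list(
        sources = sort(unique(src), method = "radix"), m = length(req),
        positions = b$positions, states = b$states)
    }
    structure(list(
      id = paste0("t:", node$name, "-", sc$output, ":", i),
      node = node$name,
      target = sunit(node$name, sc$output),
      schema = sc,
      tau = schema_enputs(sc),
      fibres = fibres), class = "t_unit")
  })
}

#' Canalyzing map of a single node
#'
#' @param node a `boolean_node`.
#' @param f2 the node's two-symbol schemata; computed from
#'   [prime_implicants()] and [two_symbol()] when omitted.
#' @return list with the node's two s-units and its t-units.
#' @export
build_cm <- function(node, f2 = NULL) {
  if (is.null(f2)) f2 <- two_symbol(prime_implicants(node))
  list(s_units = c(sunit(node$name, 0L), sunit(node$name, 1L)),
       t_units = make_tunits(node, f2))
}

#' Build the dynamics canalization map of a network
#'
#' Union of the per-node canalyzing maps over the shared s-units.
#'
#' @param net a `boolean_network`.
#' @return an object of class `dcm` with elements `s_units` (length `2n`),
#'   `t_units`, and the originating `net`.
#' @export
build_dcm <- function(net) {
  t_units <- list()
  for (nd in net$nodes) {
    cm <- build_cm(nd)
    t_units <- c(t_units, cm$t_units)
  }
  names(t_units) <- vapply(t_units, `[[`, character(1), "id")
  structure(list(s_units = s_units(net), t_units = t_units, net = net),
            class = "dcm")
}

#' @export
print.dcm <- function(x, ...) {
  cat("DCM: ", length(x$s_units), " s-units, ", length(x$t_units),
      " t-units (network of ", n_nodes(x$net), " nodes)\n", sep = "")
  invisible(x)
}

# Threshold/fibre-bundle evaluation of a t-unit on a global partial
# configuration (named 0/1/NA vector over all variables).  Each fibre's
# contribution is capped at its multiplicity m, so the total reaches tau
# exactly when every fibre is fully satisfied; for a position-free bundle
# the contribution is the size of the maximum injective assignment of the
# required states to known matching positions.
tunit_fires <- function(tu, pc_global, inputs) {
  total <- 0L
  for (fb in tu$fibres) {
    if (is.null(fb$positions)) {
      v <- pc_global[sunit_variable(fb$sources)]
      total <- total +
        as.integer(!is.na(v) && v == sunit_state(fb$sources))
    } else {
      vals <- pc_global[inputs[fb$positions]]
      r1 <- sum(fb$states == "1")
      r0 <- sum(fb$states == "0")
      c1 <- sum(!is.na(vals) & vals == 1L)
      c0 <- sum(!is.na(vals) & vals == 0L)
      total <- total + min(c1, r1) + min(c0, r0)
    }
  }
  total >= tu$tau
}

# Schema-matching evaluation of a t-unit (canonical semantics).
tunit_matches <- function(tu, pc_global, net) {
  inputs <- net$nodes[[tu$node]]$inputs
  pc <- pc_global[inputs]
  schema_match(tu$schema, unname(pc))
}

# ---------------------------------------------------------------------------
# Export / import

dcm_to_igraph <- function(dcm, simplify = FALSE) {
  tus <- dcm$t_units
  if (simplify) {
    keep <- vapply(tus, function(tu) {
      tu$tau != 1L || length(tu$fibres) != 1L ||
        length(tu$fibres[[1]]$sources) > 1L
    }, logical(1))
    tus <- tus[keep]
  }
  v_names <- c(dcm$s_units, vapply(tus, `[[`, character(1), "id"))
  v_type <- c(rep("s", length(dcm$s_units)), rep("t", length(tus)))
  v_state <- c(sunit_state(dcm$s_units), rep(NA_integer_, length(tus)))
  v_tau <- c(rep(NA_integer_, length(dcm$s_units)),
             vapply(tus, `[[`, integer(1), "tau"))
  v_label <- c(dcm$s_units,
               vapply(tus, function(tu) paste0("τ=", tu$tau), character(1)))
  edges <- character(0)
  e_delay <- integer(0)
  e_fibre <- integer(0)
  e_m <- integer(0)
  for (tu in tus) {
    for (fi in seq_along(tu$fibres)) {
      fb <- tu$fibres[[fi]]
      for (src in fb$sources) {
        edges <- c(edges, src, tu$id)
        e_delay <- c(e_delay, 0L)
        e_fibre <- c(e_fibre, fi)
        e_m <- c(e_m, fb$m)
      }
    }
    edges <- c(edges, tu$id, tu$target)
    e_delay <- c(e_delay, 1L)
    e_fibre <- c(e_fibre, NA_integer_)
    e_m <- c(e_m, NA_integer_)
  }
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(v_names), name = v_names,
                            type = v_type, state = v_state, tau = v_tau,
                            label = v_label)
  if (length(edges)) {
    g <- igraph::add_edges(g, edges, delay = e_delay, fibre = e_fibre,
                           m = e_m)
  }
  g
}

#' Export a DCM
#'
#' @param dcm a `dcm`.
#' @param format `"json"` (lossless round-trip), `"graphml"`, or `"dot"`.
#' @param file output path; required for graphml, optional for json/dot
#'   (text returned when `NULL`).
#' @param simplify drop t-units with threshold 1 and no permutation
#'   redundancy (display convention; the full map keeps them).
#' @return the serialized text for json/dot, invisibly when written.
#' @export
export_dcm <- function(dcm, format = c("json", "graphml", "dot"),
                       file = NULL, simplify = FALSE) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      s_units = dcm$s_units,
      t_units = lapply(unname(dcm$t_units), function(tu) {
        list(id = tu$id, node = tu$node, target = tu$target, tau = tu$tau,
             output = tu$schema$output,
             schema = list(
               k = tu$schema$k,
               fixed = tu$schema$fixed,
               bundles = lapply(tu$schema$bundles, function(b) {
                 list(positions = b$positions, states = b$states)
               }),
               expansion = tu$schema$expansion),
             fibres = lapply(tu$fibres, function(fb) {
               fb[c("sources", "m", "positions", "states")]
             }))
      }),
      rules = write_rules(dcm$net))
    txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
    if (is.null(file)) return(txt)
    writeLines(txt, file)
    return(invisible(txt))
  }
  g <- dcm_to_igraph(dcm, simplify = simplify)
  if (format == "graphml") {
    if (is.null(file)) stop("graphml export requires a file path")
    igraph::write_graph(g, file, format = "graphml")
    return(invisible(file))
  }
  # dot
  lines <- c("digraph DCM {")
  vdf <- igraph::as_data_frame(g, what = "vertices")
  for (i in seq_len(nrow(vdf))) {
    v <- vdf[i, ]
    attrs <- if (v$type == "s") {
      sprintf("shape=circle, style=filled, fillcolor=%s, label=\"%s\"",
              if (v$state == 1) "black, fontcolor=white" else "white", v$name)
    } else {
      sprintf("shape=diamond, label=\"%s\"", v$label)
    }
    lines <- c(lines, sprintf("  \"%s\" [%s];", v$name, attrs))
  }
  edf <- igraph::as_data_frame(g, what = "edges")
  for (i in seq_len(nrow(edf))) {
    e <- edf[i, ]
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"dt=%d\"];",
                              e$from, e$to, e$delay))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Import a DCM from its JSON export
#' @param file path or JSON text.
#' @return a `dcm` structurally identical to the exported one.
#' @export
import_dcm_json <- function(file) {
  obj <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  net <- parse_rules(obj$rules)
  t_units <- lapply(obj$t_units, function(tu) {
    fixed <- tu$schema$fixed
    bundles <- lapply(tu$schema$bundles, function(b) {
      list(positions = as.integer(unlist(b$positions)),
           states = as.character(unlist(b$states)))
    })
    sc <- two_symbol_schema(tu$schema$k, fixed, bundles, tu$output,
                            as.character(unlist(tu$schema$expansion)))
    fibres <- lapply(tu$fibres, function(fb) {
      out <- list(sources = as.character(unlist(fb$sources)),
                  m = as.integer(fb$m))
      if (!is.null(fb$positions)) {
        out$positions <- as.integer(unlist(fb$positions))
        out$states <- as.character(unlist(fb$states))
      }
      out
    })
    structure(list(id = tu$id, node = tu$node, target = tu$target,
                   schema = sc, tau = tu$tau, fibres = fibres),
              class = "t_unit")
  })
  names(t_units) <- vapply(t_units, `[[`, character(1), "id")
  structure(list(s_units = as.character(unlist(obj$s_units)),
                 t_units = t_units, net = net), class = "dcm")
}
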