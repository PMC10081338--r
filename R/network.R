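# Boolean network representation and simulation.
#
# A network is a named list of nodes; each node carries its ordered input
# list and a look-up table (LUT) in binary counting order over the inputs,
# most-significant input first.  Constant/input nodes are represented as
# self-copy identity nodes so they can be pinned like any other variable.

RESERVED_WORDS <- c("and", "or", "not", "AND", "OR", "NOT", "TRUE", "FALSE",
                    "True", "False", "true", "false")

#' Create a Boolean node
#'
#' @param name node identifier.
#' @param inputs ordered character vector of input node names (may be empty
#'   for a constant node).
#' @param lut integer vector of `2^k` output bits, one per input row in
#'   binary counting order with the first input as the most significant bit.
#' @param expr optional rule expression the node was parsed from (kept for
#'   round-tripping and lattice composition; the LUT is authoritative).
#' @return an object of class `boolean_node`.
#' @export
boolean_node <- function(name, inputs, lut, expr = NULL) {
  inputs <- as.character(inputs)
  lut <- as.integer(lut)
  k <- length(inputs)
  if (length(lut) != 2^k) {
    stop("node '", name, "': LUT has ", length(lut), " rows, expected ", 2^k)
  }
  if (any(!lut %in% c(0L, 1L))) {
    stop("node '", name, "': LUT entries must be 0 or 1")
  }
  if (anyDuplicated(inputs)) {
    stop("node '", name, "': duplicated input names")
  }
  structure(list(name = name, inputs = inputs, lut = lut, expr = expr),
            class = "boolean_node")
}

#' Create a Boolean network from a list of nodes
#'
#' @param nodes list of [boolean_node()] objects.
#' @return an object of class `boolean_network` with elements `nodes` (named
#'   list) and `edges` (two-column matrix of directed source -> target pairs).
#' @export
boolean_network <- function(nodes) {
  names(nodes) <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(names(nodes))) {
    stop("duplicate node names: ",
         paste(unique(names(nodes)[duplicated(names(nodes))]), collapse = ", "))
  }
  for (nd in nodes) {
    missing <- setdiff(nd$inputs, names(nodes))
    if (length(missing)) {
      stop("node '", nd$name, "' references undefined variable(s): ",
           paste(missing, collapse = ", "))
    }
  }
  edges <- do.call(rbind, lapply(nodes, function(nd) {
    if (length(nd$inputs) == 0) return(NULL)
    cbind(source = nd$inputs, target = rep(nd$name, length(nd$inputs)))
  }))
  if (is.null(edges)) {
    edges <- matrix(character(0), ncol = 2,
                    dimnames = list(NULL, c("source", "target")))
  }
  structure(list(nodes = nodes, edges = edges), class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  for (nd in x$nodes) {
    cat("  ", nd$name, " <- ",
        if (length(nd$inputs)) paste(nd$inputs, collapse = ", ") else "(constant)",
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of variables in a network
#' @param net a `boolean_network`.
#' @return integer n.
#' @export
n_nodes <- function(net) length(net$nodes)

#' Names of the network variables
#' @param net a `boolean_network`.
#' @export
node_names <- function(net) names(net$nodes)

# ---------------------------------------------------------------------------
# Rule-file parsing

tokenize_expr <- function(expr, line = NULL) {
  pat <- "[A-Za-z_][A-Za-z0-9_.]*|[01]|\\(|\\)|&&?|\\|\\|?|!"
  tokens <- regmatches(expr, gregexpr(pat, expr))[[1]]
  stripped <- gsub(pat, "", gsub("\\s", "", expr))
  if (nchar(gsub("\\s", "", stripped)) > 0) {
    stop("unparseable expression", if (!is.null(line)) paste0(" in rule: ", line),
         " (left over: '", stripped, "')")
  }
  tokens
}

expr_variables <- function(expr) {
  tokens <- tokenize_expr(expr)
  vars <- tokens[grepl("^[A-Za-z_]", tokens) & !(tokens %in% RESERVED_WORDS)]
  unique(vars)
}

# Translate a rule expression to an R expression using & | ! over logical
# vectors.  Token whitelist keeps eval() safe.
translate_expr <- function(expr, line = NULL) {
  tokens <- tokenize_expr(expr, line)
  out <- vapply(tokens, function(tk) {
    switch(tk,
           "and" = "&", "AND" = "&", "&" = "&", "&&" = "&",
           "or" = "|", "OR" = "|", "|" = "|", "||" = "|",
           "not" = "!", "NOT" = "!", "!" = "!",
           "TRUE" = "TRUE", "True" = "TRUE", "true" = "TRUE", "1" = "TRUE",
           "FALSE" = "FALSE", "False" = "FALSE", "false" = "FALSE", "0" = "FALSE",
           "(" = "(", ")" = ")",
           paste0("`", tk, "`"))
  }, character(1))
  parse(text = paste(out, collapse = " "))[[1]]
}

# Tabulate a rule expression over all input rows; returns the LUT in binary
# counting order (inputs[1] is the most significant bit).
tabulate_expr <- function(expr, inputs, line = NULL) {
  k <- length(inputs)
  rexpr <- translate_expr(expr, line)
  env <- new.env(parent = baseenv())
  rows <- 0:(2^k - 1)
  for (j in seq_along(inputs)) {
    assign(inputs[j], bitwAnd(bitwShiftR(rows, k - j), 1L) == 1L, envir = env)
  }
  val <- eval(rexpr, env)
  if (length(val) == 1) val <- rep(val, 2^k)
  as.integer(val)
}

# Drop inputs whose value never affects the output.
prune_fictitious <- function(inputs, lut) {
  repeat {
    k <- length(inputs)
    if (k == 0) break
    dropped <- FALSE
    for (j in seq_len(k)) {
      rows <- 0:(2^k - 1)
      bit <- bitwAnd(bitwShiftR(rows, k - j), 1L)
      lo <- lut[rows[bit == 0L] + 1L]
      hi <- lut[bitwOr(rows[bit == 0L], bitwShiftL(1L, k - j)) + 1L]
      if (all(lo == hi)) {
        inputs <- inputs[-j]
        lut <- lo
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  list(inputs = inputs, lut = lut)
}

#' Parse a Boolean rule file
#'
#' One rule per line in the form `name* = expression` with operators
#' `and`, `or`, `not` (also `& | !`) and parentheses.  Lines starting with
#' `#` and blank lines are ignored.  Constant inputs may be written as
#' self-copies (`i1* = i1`) or as bare constants (`c* = 0`).  Inputs whose
#' value never affects the output (fictitious inputs) are pruned during
#' tabulation.
#'
#' @param text character scalar (whole file) or vector of lines.
#' @return a `boolean_network`.
#' @export
parse_rules <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rules <- list()
  for (ln in lines) {
    m <- regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\*?\\s*=\\s*(.+)$", ln)
    parts <- regmatches(ln, m)[[1]]
    if (length(parts) != 3) stop("unparseable rule line: '", ln, "'")
    name <- parts[2]
    if (name %in% names(rules)) stop("duplicate rule for node '", name, "'")
    rules[[name]] <- parts[3]
  }
  all_names <- names(rules)
  nodes <- lapply(all_names, function(name) {
    expr <- rules[[name]]
    vars <- expr_variables(expr)
    missing <- setdiff(vars, all_names)
    if (length(missing)) {
      stop("rule for '", name, "' references undefined variable(s): ",
           paste(missing, collapse = ", "))
    }
    lut <- tabulate_expr(expr, vars, paste0(name, "* = ", expr))
    pr <- prune_fictitious(vars, lut)
    boolean_node(name, pr$inputs, pr$lut, expr = expr)
  })
  boolean_network(nodes)
}

#' Read a Boolean rule file from disk
#' @param path file path.
#' @return a `boolean_network`.
#' @export
read_rules <- function(path) parse_rules(readLines(path, warn = FALSE))

#' Write a network as a canonical rule file
#'
#' Each node's rule is emitted as a disjunction of minterms of its LUT so
#' that re-parsing reproduces identical LUTs and wiring (networks without
#' fictitious inputs round-trip exactly).
#'
#' @param net a `boolean_network`.
#' @param path optional file path; when `NULL` the text is returned.
#' @return rule text, invisibly when written to a file.
#' @export
write_rules <- function(net, path = NULL) {
  lines <- vapply(net$nodes, function(nd) {
    k <- length(nd$inputs)
    on_rows <- which(nd$lut == 1L) - 1L
    expr <- if (length(on_rows) == 0) {
      "0"
    } else if (length(on_rows) == 2^k) {
      if (k == 0) "1" else paste0("1")
    } else {
      terms <- vapply(on_rows, function(r) {
        lits <- vapply(seq_len(k), function(j) {
          bit <- bitwAnd(bitwShiftR(r, k - j), 1L)
          if (bit == 1L) nd$inputs[j] else paste0("not ", nd$inputs[j])
        }, character(1))
        paste0("(", paste(lits, collapse = " and "), ")")
      }, character(1))
      paste(terms, collapse = " or ")
    }
    paste0(nd$name, "* = ", expr)
  }, character(1))
  text <- paste(lines, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}

#' Read a network from an explicit look-up-table file
#'
#' Tab-separated columns `node`, `inputs` (comma-separated, empty for a
#' constant node) and `outputs` (string of `2^k` bits in binary counting
#' order, first input most significant).
#'
#' @param path file path or a character vector of lines.
#' @return a `boolean_network`.
#' @export
read_lut_table <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    path
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^node\\t", lines[1])) lines <- lines[-1]
  nodes <- lapply(lines, function(ln) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      fields <- c(fields, rep("", 3 - length(fields)))
    }
    inputs <- strsplit(fields[2], ",", fixed = TRUE)[[1]]
    inputs <- trimws(inputs[nzchar(trimws(inputs))])
    bits <- as.integer(strsplit(fields[3], "")[[1]])
    boolean_node(fields[1], inputs, bits)
  })
  boolean_network(nodes)
}

#' Write a network as a look-up-table TSV
#' @param net a `boolean_network`.
#' @param path optional path; when `NULL` the text is returned.
#' @export
write_lut_table <- function(net, path = NULL) {
  lines <- c("node\tinputs\toutputs",
             vapply(net$nodes, function(nd) {
               paste(nd$name, paste(nd$inputs, collapse = ","),
                     paste(nd$lut, collapse = ""), sep = "\t")
             }, character(1)))
  text <- paste(lines, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}

# ---------------------------------------------------------------------------
# Synchronous dynamics

# Evaluate one node on a full configuration (named 0/1 vector).
eval_node <- function(nd, config) {
  k <- length(nd$inputs)
  if (k == 0) return(nd$lut[1L])
  idx <- 0L
  for (j in seq_len(k)) {
    idx <- bitwOr(bitwShiftL(idx, 1L), as.integer(config[[nd$inputs[j]]]))
  }
  nd$lut[idx + 1L]
}

#' Synchronous update of a full configuration
#'
#' All variables are replaced simultaneously by their LUT output on the
#' current input values.
#'
#' @param net a `boolean_network`.
#' @param config named vector of 0/1 states covering every variable.
#' @return the next full configuration (named integer vector).
#' @export
synchronous_step <- function(net, config) {
  vars <- node_names(net)
  if (!all(vars %in% names(config))) {
    stop("configuration is missing variables: ",
         paste(setdiff(vars, names(config)), collapse = ", "))
  }
  config <- config[vars]
  if (anyNA(config) || any(!config %in% c(0L, 1L))) {
    stop("synchronous_step requires a full 0/1 configuration (no unknowns)")
  }
  out <- vapply(net$nodes, eval_node, integer(1), config = config)
  names(out) <- vars
  out
}

# ---------------------------------------------------------------------------
# Integer-coded exhaustive simulation (oracle machinery)
#
# Configurations are encoded as integers with node j (in network order) on
# bit (n - j), so the code reads like the configuration written left to
# right.  All maps are vectorised over configuration vectors.

config_to_int <- function(net, config) {
  vars <- node_names(net)
  n <- length(vars)
  code <- 0L
  for (j in seq_len(n)) {
    code <- bitwOr(bitwShiftL(code, 1L), as.integer(config[[vars[j]]]))
  }
  code
}

int_to_config <- function(net, code) {
  vars <- node_names(net)
  n <- length(vars)
  out <- vapply(seq_len(n), function(j) bitwAnd(bitwShiftR(code, n - j), 1L),
                integer(1))
  names(out) <- vars
  out
}

# Vectorised synchronous successor over integer-coded configurations, with
# the variables in `pin_bits` (named 0/1) overwritten each step.
step_codes <- function(net, codes, pinned = integer(0)) {
  vars <- node_names(net)
  n <- length(vars)
  nxt <- integer(length(codes))
  for (j in seq_len(n)) {
    nd <- net$nodes[[j]]
    k <- length(nd$inputs)
    if (k == 0) {
      out <- rep(nd$lut[1L], length(codes))
    } else {
      idx <- integer(length(codes))
      for (m in seq_len(k)) {
        p <- match(nd$inputs[m], vars)
        bit <- bitwAnd(bitwShiftR(codes, n - p), 1L)
        idx <- bitwOr(bitwShiftL(idx, 1L), bit)
      }
      out <- nd$lut[idx + 1L]
    }
    nxt <- bitwOr(bitwShiftL(nxt, 1L), out)
  }
  if (length(pinned)) {
    for (v in names(pinned)) {
      p <- match(v, vars)
      mask <- bitwShiftL(1L, n - p)
      nxt <- if (pinned[[v]] == 1L) bitwOr(nxt, mask) else bitwAnd(nxt, bitwNot(mask))
    }
  }
  nxt
}

#' Exhaustive stabilization oracle
#'
#' Simulates every completion of the unpinned variables, holding the pinned
#' variables fixed at every step, until all trajectories reach their
#' attractors.  Returns the (variable, state) pairs that hold at every time
#' step of every reached attractor; these are the states guaranteed to
#' stabilize under the pinning regardless of the unknown initial condition.
#'
#' @param net a `boolean_network`.
#' @param pinned named vector of 0/1 states for the pinned variables (may be
#'   empty).
#' @param cap maximum number of free variables (default 20); exceeding it is
#'   an error because the enumeration is exponential.
#' @return named integer vector: stabilized variables and their states.
#' @export
brute_force_stabilization <- function(net, pinned = integer(0), cap = 20L) {
  vars <- node_names(net)
  n <- length(vars)
  if (length(pinned)) {
    if (!all(names(pinned) %in% vars)) {
      stop("pinned refers to unknown variables: ",
           paste(setdiff(names(pinned), vars), collapse = ", "))
    }
    if (any(!pinned %in% c(0L, 1L))) stop("pinned states must be 0 or 1")
  }
  free <- setdiff(vars, names(pinned))
  if (length(free) > cap) {
    stop("number of free variables (", length(free), ") exceeds cap (", cap, ")")
  }
  # All completions of the free variables.
  codes <- 0L
  for (j in seq_len(n)) {
    v <- vars[j]
    if (v %in% names(pinned)) {
      codes <- bitwOr(bitwShiftL(codes, 1L), as.integer(pinned[[v]]))
    } else {
      codes <- c(bitwShiftL(codes, 1L), bitwOr(bitwShiftL(codes, 1L), 1L))
    }
  }
  # Forward closure of the initial set under the pinned map.
  reach <- unique(codes)
  frontier <- reach
  repeat {
    nxt <- unique(step_codes(net, frontier, pinned))
    frontier <- setdiff(nxt, reach)
    if (!length(frontier)) break
    reach <- c(reach, frontier)
  }
  # Attractor states = closure states surviving iterated image restriction.
  cur <- reach
  repeat {
    img <- unique(step_codes(net, cur, pinned))
    keep <- intersect(cur, img)
    if (length(keep) == length(cur)) break
    cur <- keep
  }
  att <- cur
  out <- integer(0)
  for (j in seq_len(n)) {
    bits <- bitwAnd(bitwShiftR(att, n - j), 1L)
    if (length(att) && all(bits == bits[1])) {
      out[vars[j]] <- bits[1]
    }
  }
  out
}

#' Enumerate the attractors of a (small) Boolean network
#'
#' Exhaustive over all `2^n` configurations under synchronous update.
#'
#' @param net a `boolean_network` with at most `cap` variables.
#' @param cap maximum network size (default 20).
#' @return list of attractors; each is an integer matrix with one row per
#'   cycle state (columns = variables).
#' @export
enumerate_attractors <- function(net, cap = 20L) {
  vars <- node_names(net)
  n <- length(vars)
  if (n > cap) stop("network size ", n, " exceeds cap ", cap)
  all_codes <- 0:(2^n - 1)
  cur <- all_codes
  repeat {
    img <- unique(step_codes(net, cur))
    keep <- intersect(cur, img)
    if (length(keep) == length(cur)) break
    cur <- keep
  }
  seen <- integer(0)
  attractors <- list()
  for (s in cur) {
    if (s %in% seen) next
    cyc <- s
    x <- step_codes(net, s)
    while (x != s) {
      cyc <- c(cyc, x)
      x <- step_codes(net, x)
    }
    seen <- c(seen, cyc)
    mat <- matrix(unlist(lapply(cyc, function(code) int_to_config(net, code))),
                  ncol = n, byrow = TRUE, dimnames = list(NULL, vars))
    attractors[[length(attractors) + 1]] <- mat
  }
  attractors
}

# ---------------------------------------------------------------------------
# Lattice composition

#' Lattice composition specification
#'
#' @param template a `boolean_network` for one cell.
#' @param cells number of cells in the linear lattice.
#' @param coupling named list mapping a template input-node name to an
#'   expression over neighbour-cell node names with relative offsets in
#'   square brackets, e.g. `list(nWG = "WG[-1] or WG[+1]")`.  Coupled input
#'   nodes are removed from each cell and every reference to them is
#'   replaced by the expression.
#' @param boundary `"periodic"` or `"open"`.
#' @return an object of class `lattice_spec`.
#' @export
lattice_spec <- function(template, cells, coupling = list(),
                         boundary = c("periodic", "open")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(template, "boolean_network"), cells >= 1)
  missing <- setdiff(names(coupling), node_names(template))
  if (length(missing)) {
    stop("coupling references missing template node(s): ",
         paste(missing, collapse = ", "))
  }
  structure(list(template = template, cells = as.integer(cells),
                 coupling = coupling, boundary = boundary),
            class = "lattice_spec")
}

# Resolve "name[offset]" references in a coupling expression for cell i.
resolve_coupling_expr <- function(expr, cell, cells, boundary, template_names) {
  pat <- "([A-Za-z_][A-Za-z0-9_.]*)\\[\\s*([+-]?[0-9]+)\\s*\\]"
  m <- gregexpr(pat, expr)
  refs <- regmatches(expr, m)[[1]]
  for (ref in unique(refs)) {
    parts <- regmatches(ref, regexec(pat, ref))[[1]]
    nm <- parts[2]
    off <- as.integer(parts[3])
    if (!nm %in% template_names) {
      stop("coupling expression references missing template node '", nm, "'")
    }
    j <- cell + off
    if (boundary == "periodic") {
      j <- ((j - 1) %% cells) + 1
    } else if (j < 1 || j > cells) {
      stop("coupling offset ", off, " escapes the open boundary at cell ", cell)
    }
    expr <- gsub(ref, paste0(nm, "_", j), expr, fixed = TRUE)
  }
  expr
}

#' Compose a multicellular network from a single-cell template
#'
#' Replicates the template over `cells` cells of a linear lattice, suffixing
#' node names with the cell index.  Inputs named in the coupling map are
#' dropped and every reference to them is replaced by the supplied
#' expression over neighbour-cell nodes; LUTs are re-tabulated.
#'
#' @param spec a [lattice_spec()].
#' @return the composed `boolean_network`.
#' @export
compose_lattice <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  template <- spec$template
  cells <- spec$cells
  coupled <- names(spec$coupling)
  tnames <- node_names(template)
  kept <- setdiff(tnames, coupled)
  lines <- character(0)
  for (i in seq_len(cells)) {
    for (nm in kept) {
      nd <- template$nodes[[nm]]
      expr <- nd$expr
      if (is.null(expr)) {
        expr <- sub("^[^=]*=\\s*", "",
                    strsplit(write_rules(boolean_network(list(nd))), "\n")[[1]][1])
      }
      # Protect/replace variable tokens: coupled -> expression, kept -> name_i
      tokens <- tokenize_expr(expr)
      out <- vapply(tokens, function(tk) {
        if (tk %in% coupled) {
          paste0("(",
                 resolve_coupling_expr(spec$coupling[[tk]], i, cells,
                                       spec$boundary, tnames),
                 ")")
        } else if (grepl("^[A-Za-z_]", tk) && !(tk %in% RESERVED_WORDS)) {
          paste0(tk, "_", i)
        } else tk
      }, character(1))
      lines <- c(lines, paste0(nm, "_", i, "* = ", paste(out, collapse = " ")))
    }
  }
  parse_rules(lines)
}

# ---------------------------------------------------------------------------
# Random network generation

#' Generate a random Boolean network
#'
#' Each node receives `k` distinct random inputs and a LUT of i.i.d.
#' Bernoulli(`bias`) output bits.  The generator uses its own RNG stream so
#' an identical seed always yields an identical network.
#'
#' @param n number of nodes.
#' @param k in-degree (0 <= k <= n).
#' @param bias probability of a 1 output per LUT row.
#' @param seed integer seed.
#' @return a `boolean_network` with nodes `x1..xn`.
#' @export
generate_random_bn <- function(n, k, bias = 0.5, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  if (bias < 0 || bias > 1) stop("bias must be in [0, 1]")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  vars <- paste0("x", seq_len(n))
  nodes <- lapply(seq_len(n), function(j) {
    inputs <- sample(vars, k)
    lut <- as.integer(stats::runif(2^k) < bias)
    boolean_node(vars[j], inputs, lut)
  })
  boolean_network(nodes)
}
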