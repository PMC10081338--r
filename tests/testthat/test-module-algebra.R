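m_ <- function(seeds, mode = "pinning") unfold(grn_dcm, seeds, mode = mode)

test_that("the four canonical interaction classes are recovered", {
  # P1-0's wake is contained in i1-0's
  ci <- classify_interaction(m_("P1-0"), m_("i1-0"), grn_dcm)
  expect_true(ci$subsumed)
  expect_true(ci$temporally_subsumed)
  expect_false(ci$synergy)

  # P1-1 and i1-1 touch disjoint halves of the map
  ci <- classify_interaction(m_("P1-1"), m_("i1-1"), grn_dcm)
  expect_true(ci$decoupled)
  expect_false(ci$obstruction)
  expect_false(ci$synergy)

  # pinning P1 ON blocks the OFF cascade that P2-1 would trigger
  ci <- classify_interaction(m_("P1-1"), m_("P2-1"), grn_dcm)
  expect_true(ci$obstruction)
  expect_true(all(c("P1-0", "g2-0") %in% ci$obstruction_witness))
  expect_false(ci$decoupled)

  # P1 ON plus i2 ON jointly fire P2-1 which neither reaches alone
  ci <- classify_interaction(m_("P1-1"), m_("i2-1"), grn_dcm)
  expect_true(ci$synergy)
  expect_equal(ci$synergy_witness, "P2-1")
})

test_that("interaction flags are symmetric and honor seed contradictions", {
  pairs <- list(c("P1-1", "i1-1"), c("P1-1", "P2-1"), c("P1-1", "i2-1"),
                c("i1-0", "i2-0"))
  for (p in pairs) {
    a <- classify_interaction(m_(p[1]), m_(p[2]), grn_dcm)
    b <- classify_interaction(m_(p[2]), m_(p[1]), grn_dcm)
    expect_equal(a$synergy, b$synergy, info = paste(p, collapse = " vs "))
    expect_equal(a$obstruction, b$obstruction)
    expect_equal(a$decoupled, b$decoupled)
  }
  ci <- classify_interaction(m_("P1-1"), m_("P1-0"), grn_dcm)
  expect_true(ci$seed_contradiction)
  expect_true(ci$obstruction)
  expect_false(ci$synergy)
  expect_error(classify_interaction(m_("P1-1"), m_("i1-1", mode = "pulse"),
                                    grn_dcm), "mode")
})

test_that("set-algebra identities hold across random module pairs", {
  for (seed in 1:15) {
    net <- generate_random_bn(8, 2, bias = 0.5, seed = seed + 300)
    dcm <- build_dcm(net)
    vars <- node_names(net)
    mods <- lapply(vars[1:5], function(v) unfold(dcm, stats::setNames(1L, v)))
    for (i in 1:4) for (j in (i + 1):5) {
      ci <- classify_interaction(mods[[i]], mods[[j]], dcm)
      if (ci$seed_contradiction) next
      Si <- mods[[i]]$module_set
      Sj <- mods[[j]]$module_set
      Sij <- ci$combined$module_set
      if (!ci$obstruction && !ci$synergy) {
        expect_true(setequal(Sij, union(Si, Sj)))
      }
      if (!ci$obstruction && ci$synergy) {
        expect_true(all(union(Si, Sj) %in% Sij))
        expect_gt(length(Sij), length(union(Si, Sj)))
      }
      if (ci$decoupled) {
        expect_equal(length(Sij), length(Si) + length(Sj))
      }
    }
  }
})

test_that("pathway-module enumeration counts all consistent seed sets", {
  p1 <- enumerate_pathway_modules(grn_dcm, 1)
  expect_length(p1, 12)   # 2 * 6 s-units
  p2 <- enumerate_pathway_modules(grn_dcm, 2)
  expect_length(p2, 60)   # 2^2 * choose(6, 2)
  expect_error(enumerate_pathway_modules(grn_dcm, 2, cap = 10), "cap")
})

test_that("maximality keeps exactly the six known s = 1 modules", {
  p1 <- enumerate_pathway_modules(grn_dcm, 1)
  lam1 <- maximal_modules(list(p1), 1)
  expect_setequal(vapply(lam1, seed_units_of, character(1)),
                  c("i1-1", "i1-0", "i2-1", "i2-0", "P1-1", "P2-1"))
  # g1-1's singleton wake is strictly inside i1-1's
  g1 <- p1[[which(vapply(p1, seed_units_of, character(1)) == "g1-1")]]
  expect_false(seed_units_of(g1) %in%
                 vapply(lam1, seed_units_of, character(1)))
  # a module covering the whole map is always maximal
  full <- unfold(grn_dcm, c(i1 = 1L, i2 = 0L))
  expect_true(all(vapply(list(full), function(m) {
    !any(vapply(p1, function(o) {
      length(m$module_set) < length(o$module_set) &&
        all(m$module_set %in% o$module_set)
    }, logical(1)))
  }, logical(1))))
})

test_that("complex and core modules follow the synergy bipartition test", {
  catalog <- module_catalog(grn_dcm, s_max = 2)
  expect_equal(catalog$counts$pathway, c(12L, 60L))
  expect_equal(catalog$counts$complex[1], 6L)  # I_1 = Lambda_1
  expect_setequal(
    vapply(catalog$complex[[1]], seed_units_of, character(1)),
    vapply(catalog$maximal[[1]], seed_units_of, character(1)))
  # the formal bipartition test admits four s = 2 complex modules; the
  # maximal-seed (core) filter keeps the two whose single seeds are
  # themselves maximal
  expect_equal(catalog$counts$complex[2], 4L)
  expect_setequal(vapply(catalog$core[[2]], seed_units_of, character(1)),
                  c("P1-1,i2-1", "i1-1,i2-0"))
  dropped <- setdiff(vapply(catalog$complex[[2]], seed_units_of, character(1)),
                     vapply(catalog$core[[2]], seed_units_of, character(1)))
  expect_true(all(grepl("g2-", dropped)))  # non-maximal g2 seeds
  # hierarchy: core <= complex <= maximal <= all, per size
  for (s in 1:2) {
    expect_lte(catalog$counts$core[s], catalog$counts$complex[s])
    expect_lte(catalog$counts$complex[s], catalog$counts$maximal[s])
    expect_lte(catalog$counts$maximal[s], catalog$counts$pathway[s])
  }
})

test_that("per-cell complex modules of the lattice are index translations", {
  lat <- load_fixture("example_grn_lattice4")
  dcm <- build_dcm(lat)
  p1 <- enumerate_pathway_modules(dcm, 1)
  lam1 <- maximal_modules(list(p1), 1)
  seeds <- vapply(lam1, seed_units_of, character(1))
  # translate each cell-1 module's set to every other cell: same module up
  # to the cell-index rotation
  cell1 <- lam1[grepl("_1-", seeds)]
  key_of <- function(mm) paste(sort(mm$module_set), collapse = "|")
  keys <- vapply(lam1, key_of, character(1))
  for (by in 1:3) {
    for (mm in cell1) {
      tr <- function(units) {
        vapply(units, function(u) {
          m <- regmatches(u, regexec("^(.*)_([0-9]+)-([01])$", u))[[1]]
          cell <- (as.integer(m[3]) - 1 + by) %% 4 + 1
          paste0(m[2], "_", cell, "-", m[4])
        }, character(1), USE.NAMES = FALSE)
      }
      expect_true(paste(sort(tr(mm$module_set)), collapse = "|") %in% keys)
    }
  }
})
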