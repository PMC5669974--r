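test_that("ratio computation handles degenerate intensities with flags", {
  r <- compute_ratio(c(25336.48, 36680.49, 0, 0, 7),
                     c(6075.38, 0, 15994.50, 0, 7))
  expect_equal(round(r$ratio[1], 2), 0.24)
  expect_equal(r$flag, c("ok", "zero", "undefined-high", "uninformative", "ok"))
  expect_equal(r$ratio[5], 1.0)
  expect_error(compute_ratio(-1, 2), "non-negative")
  expect_error(compute_ratio(1, c(1, 2)), "length")
})

test_that("fixture table loads with 51 endpoints and recomputed ratios", {
  tab <- fixture_table()
  ep <- tab$endpoints
  expect_equal(nrow(ep), 51)
  expect_false(anyDuplicated(ep$antibody) > 0)
  expect_equal(round(ep$ratio[ep$antibody == "c-Kit (Y703)"], 2), 3.55)
  expect_equal(round(ep$ratio[ep$antibody == "b-Raf (S445)"], 2), 0.24)
  expect_equal(ep$flag[ep$antibody == "BAD (S155)"], "undefined-high")
  expect_equal(ep$ratio[ep$antibody == "Src (Y527)"], 0)
})

test_that("malformed tables are rejected", {
  empty <- tempfile(fileext = ".csv")
  writeLines("catalog_id,antibody,l_OS,s_OS", empty)
  expect_error(load_rppa_table(empty), "no endpoint rows")

  nocol <- tempfile(fileext = ".csv")
  writeLines(c("catalog_id,antibody,l_OS", "1,x,2"), nocol)
  expect_error(load_rppa_table(nocol), "missing column")

  neg <- tempfile(fileext = ".csv")
  writeLines(c("catalog_id,antibody,l_OS,s_OS", "1,x,-5,2"), neg)
  expect_error(load_rppa_table(neg), "negative intensity")

  expect_error(load_rppa_table(tempfile()), "not found")
})

test_that("two-fold rule selects 20 divergent endpoints (4 up, 16 down)", {
  sel <- select_divergent(fixture_table(), fold = 2)
  expect_equal(sel$n_divergent, 20)
  expect_equal(sel$n_up, 4)
  expect_equal(sel$n_down, 16)
  expect_true("BAD (S155)" %in% sel$up_in_sOS$antibody)
  expect_true("Src (Y527)" %in% sel$down_in_sOS$antibody)
  expect_length(intersect(sel$up_in_sOS$antibody, sel$down_in_sOS$antibody), 0)
})

test_that("divergence selection is monotone in the fold threshold", {
  tab <- fixture_table()
  folds <- c(1.2, 1.5, 2, 3, 5, 10)
  counts <- vapply(folds, function(f) select_divergent(tab, f)$n_divergent,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(select_divergent(tab, fold = 1), "> 1")
})

test_that("phosphosite aggregation takes geometric means of finite ratios", {
  tab <- fixture_table()
  agg <- aggregate_phosphosites(tab, load_antibody_map())
  gm <- function(x) exp(mean(log(x)))
  ep <- tab$endpoints
  r <- function(ab) ep$ratio[ep$antibody == ab]
  expect_equal(agg$ratio[agg$node == "cKIT"],
               gm(c(r("c-Kit (Y703)"), r("cKit (Y719)"))))
  expect_equal(round(agg$ratio[agg$node == "cKIT"], 2), 2.69)
  # S371/T389 only; T412 is excluded from the aggregate
  expect_equal(agg$ratio[agg$node == "p70S6K"],
               gm(c(r("p70S6 Kinase (S371)"), r("p70S6 Kinase (T389)"))))
  expect_equal(round(agg$ratio[agg$node == "p70S6K"], 2), 0.41)
  # single-endpoint node keeps its own ratio
  expect_equal(agg$ratio[agg$node == "ERK"], r("ERK 1/2 (T202/Y204)"))
  # BAD's undefined-high endpoint does not enter the mean
  expect_equal(agg$ratio[agg$node == "BAD"], r("BAD (S136)"))
  expect_equal(agg$n_finite[agg$node == "BAD"], 1)
})

test_that("aggregation is invariant to endpoint row order", {
  tab <- fixture_table()
  map <- load_antibody_map()
  set.seed(7)
  shuffled <- tab
  shuffled$endpoints <- tab$endpoints[sample(nrow(tab$endpoints)), ]
  expect_equal(aggregate_phosphosites(shuffled, map),
               aggregate_phosphosites(tab, map),
               ignore_attr = TRUE)
})

test_that("unmapped antibodies raise a mapping error naming them", {
  tab <- fixture_table()
  map <- load_antibody_map()
  map <- map[map$antibody != "Bax", ]
  expect_error(aggregate_phosphosites(tab, map), "Bax")
})

test_that("calibration proteins are BAD/cKIT up and RAF/p70S6K down", {
  tab <- fixture_table()
  map <- load_antibody_map()
  nodes <- build_default_model()$nodes$name
  sel <- select_calibration_proteins(tab, map, nodes, k_per_side = 2)
  cp <- sel$calibration_proteins
  expect_setequal(cp$node[cp$direction == "+"], c("BAD", "cKIT"))
  expect_setequal(cp$node[cp$direction == "-"], c("RAF", "p70S6K"))

  sel1 <- select_calibration_proteins(tab, map, nodes, k_per_side = 1)
  cp1 <- sel1$calibration_proteins
  expect_equal(cp1$node[cp1$direction == "+"], "BAD")
  expect_equal(cp1$node[cp1$direction == "-"], "RAF")
})

test_that("a table without divergence yields a selection error", {
  flat <- fixture_table()
  flat$endpoints$value_sOS <- flat$endpoints$value_lOS
  flat$endpoints$ratio <- 1
  flat$endpoints$flag <- "ok"
  map <- load_antibody_map()
  nodes <- build_default_model()$nodes$name
  expect_error(select_calibration_proteins(flat, map, nodes), "selection error")
  expect_equal(select_divergent(flat, 1 + 1e-9)$n_divergent, 0)
})
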