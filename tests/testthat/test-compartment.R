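test_that("core criteria match the worked example and a brute-force scan", {
  ex <- worked_micro_example()
  core <- core_microbiome(ex$counts, ex$metadata)
  expect_setequal(core$members$otu_id, ex$expected$core)
  expect_equal(core$fraction_of_reads,
               sum(ex$counts$counts[ex$expected$core, ]) /
                 sum(ex$counts$counts))
  # brute-force equivalence on random tables (presence can be marginal)
  set.seed(18)
  meta <- std_metadata()
  for (r in 1:10) {
    tab <- random_table(60, lambda = 2)
    got <- core_microbiome(tab, meta)$members$otu_id
    expect_setequal(got, brute_core(tab$counts, meta))
  }
})

test_that("scoped cores restrict the criteria to one depth", {
  ex <- worked_micro_example()
  expect_setequal(scoped_core(ex$counts, ex$metadata, "topsoil")$members$otu_id,
                  ex$expected$topsoil_core)
  # scope=all is core_microbiome
  a <- scoped_core(ex$counts, ex$metadata, "all")
  b <- core_microbiome(ex$counts, ex$metadata)
  expect_identical(a$members, b$members)
  # an OTU absent from subsoil can be topsoil-core but never all-core
  expect_true("Otu05" %in%
                scoped_core(ex$counts, ex$metadata, "topsoil")$members$otu_id)
  expect_false("Otu05" %in% b$members$otu_id)
  # a cell with too few replicates is an error
  meta <- ex$metadata
  expect_error(core_microbiome(
    count_table(ex$counts$counts[, -(1:2)]), meta[-(1:2), ]),
    "fewer than 2 replicates")
})

test_that("ternary coordinates land on tips, center and respect the cutoff", {
  ex <- worked_micro_example()
  tc <- ternary_coordinates(ex$counts, ex$metadata)
  r3 <- tc[tc$otu_id == "Otu03", ]
  expect_equal(unlist(r3[, c("bulk", "drilosphere", "rhizosphere")]),
               c(bulk = 0, drilosphere = 0, rhizosphere = 1))
  r6 <- tc[tc$otu_id == "Otu06", ]
  expect_equal(r6$bulk, 1)
  expect_false("Otu10" %in% tc$otu_id)         # total abundance 1 < 5
  expect_equal(rowSums(tc[, c("bulk", "drilosphere", "rhizosphere")]),
               rep(1, nrow(tc)), tolerance = 1e-9)
  # equal means in all compartments -> the center
  meta <- std_metadata()
  m <- matrix(10, 2, 18, dimnames = list(c("x", "y"), meta$sample_id))
  tcc <- ternary_coordinates(count_table(m), meta)
  expect_equal(unlist(tcc[1, c("bulk", "drilosphere", "rhizosphere")]),
               c(bulk = 1, drilosphere = 1, rhizosphere = 1) / 3,
               tolerance = 1e-12)
  # replicate-mean before closure: inflating one replicate's depth uniformly
  # (counts doubled, relative abundances unchanged) leaves coordinates alone
  set.seed(19)
  tab <- random_table(20, lambda = 15)
  t1 <- ternary_coordinates(tab, meta)
  m2 <- tab$counts; m2[, 4] <- m2[, 4] * 2
  t2 <- ternary_coordinates(count_table(m2), meta)
  shared <- intersect(t1$otu_id, t2$otu_id)
  expect_equal(t1[match(shared, t1$otu_id), c("bulk", "drilosphere")],
               t2[match(shared, t2$otu_id), c("bulk", "drilosphere")],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("cluster attribution finds home cells and flags ties", {
  meta <- std_metadata()
  m <- matrix(1, 4, 18, dimnames = list(c("r1", "r2", "b1", "flat"),
                                        meta$sample_id))
  rh <- meta$compartment == "rhizosphere" & meta$depth == "topsoil"
  m[c("r1", "r2"), rh] <- 60
  m["b1", meta$compartment == "bulk" & meta$depth == "subsoil"] <- 40
  part <- c(r1 = 1L, r2 = 1L, b1 = 2L, flat = 3L)
  att <- attribute_clusters(part, count_table(m), meta)
  a <- att$attribution
  expect_identical(a$compartment[a$community == 1], "rhizosphere")
  expect_identical(a$depth[a$community == 1], "topsoil")
  expect_identical(a$compartment[a$community == 2], "bulk")
  expect_identical(a$depth[a$community == 2], "subsoil")
  expect_equal(unname(rowSums(att$profiles)), rep(1, 3), tolerance = 1e-12)
  expect_length(att$sample_order, 18)
  # attribution cell is the argmax of the profile
  for (i in seq_len(nrow(a))) {
    cell <- paste(a$depth[i], a$compartment[i], sep = ".")
    expect_equal(unname(att$profiles[i, cell]), max(att$profiles[i, ]))
  }
})

test_that("planted clusters attribute to their home cells", {
  # a calm shared factor keeps replicate cell means close to expectation,
  # so the home-cell argmax is decisive for any seed
  ds <- generate_dataset(synthetic_design(cluster_sd = 0.5, seed = 30))
  sub <- subsample_counts(ds$counts, seed = 31)
  truth <- ds$truth$labels
  part <- setNames(match(truth, paste0("cluster", 1:4)), names(truth))
  part <- part[!is.na(part)]
  att <- attribute_clusters(part, sub, ds$metadata)
  got <- att$attribution
  want <- ds$truth$cluster_cells
  expect_identical(got$depth, want$depth)
  expect_identical(got$compartment, want$compartment)
})

test_that("the whole-table community has a flat profile on exchangeable data", {
  tab <- null_table(seed = 32)
  meta <- std_metadata()
  part <- setNames(rep(1L, nrow(tab$counts)), otu_ids(tab))
  att <- attribute_clusters(part, tab, meta)
  expect_equal(unname(att$profiles[1, ]), rep(1 / 6, 6), tolerance = 0.02)
})

test_that("cross-cluster negative tables mirror the edge tally", {
  ids <- c("a", "b", "c", "d")
  rho <- diag(4); dimnames(rho) <- list(ids, ids)
  p <- matrix(1, 4, 4, dimnames = dimnames(rho))
  rho["a", "b"] <- rho["b", "a"] <- -0.9; p["a", "b"] <- p["b", "a"] <- 0.001
  net <- build_network(rho, p)
  part <- c(a = 1L, b = 2L, c = 1L, d = 2L)
  tab <- cross_cluster_negative_table(net, part)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$otu_id[tab$cluster_from == "1"], "b")
  expect_identical(tab$otu_id[tab$cluster_from == "2"], "a")
  # no negative edges -> empty table
  rho["a", "b"] <- rho["b", "a"] <- 0.9
  expect_identical(nrow(cross_cluster_negative_table(build_network(rho, p),
                                                     part)), 0L)
})

test_that("negative tables equal brute-force tallies on random networks", {
  set.seed(20)
  for (r in 1:10) {
    n <- 12
    rho <- matrix(runif(n * n, -1, 1), n, n)
    rho[lower.tri(rho)] <- t(rho)[lower.tri(rho)]
    diag(rho) <- 1
    p <- matrix(runif(n * n, 0, 0.1), n, n)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    ids <- sprintf("o%02d", 1:n)
    dimnames(rho) <- dimnames(p) <- list(ids, ids)
    net <- build_network(rho, p)
    part <- setNames(sample(1:3, n - 2, replace = TRUE), ids[1:(n - 2)])
    got <- cross_cluster_negative_table(net, part)
    want <- brute_negative_tally(net$edges, part)
    expect_identical(nrow(got), length(want))
    for (i in seq_len(nrow(got))) {
      key <- paste(got$cluster_from[i], got$cluster_to[i], got$otu_id[i],
                   sep = "\r")
      expect_identical(got$n_negative[i], as.integer(want[[key]]))
    }
  }
})

test_that("shared-OTU Venn cells equal brute-force set algebra", {
  meta <- std_metadata()
  m <- matrix(5, 1, 18, dimnames = list("everywhere", meta$sample_id))
  sh <- shared_otu_summary(count_table(m), meta)
  triple <- sh[sh$bulk & sh$drilosphere & sh$rhizosphere, ]
  expect_equal(triple$n_otus, c(1, 1))
  expect_equal(sum(sh$n_otus), 2)   # only the triple cell is occupied
  set.seed(21)
  tab <- random_table(20, lambda = 1)
  sh2 <- shared_otu_summary(tab, meta)
  for (i in seq_len(nrow(sh2))) {
    pres <- vapply(c("bulk", "drilosphere", "rhizosphere"), function(cp) {
      idx <- meta$depth == sh2$depth[i] & meta$compartment == cp
      rowSums(tab$counts[, idx, drop = FALSE] > 0) > 0
    }, logical(20))
    want <- sum(pres[, 1] == sh2$bulk[i] & pres[, 2] == sh2$drilosphere[i] &
                  pres[, 3] == sh2$rhizosphere[i])
    expect_identical(sh2$n_otus[i], want)
  }
  # empty table -> all-zero cells
  e <- count_table(m[0, , drop = FALSE])
  expect_true(all(shared_otu_summary(e, meta)$n_otus == 0))
})
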