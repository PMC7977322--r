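test_that("the founder-and-offspring trio partitions to the published values", {
  p <- partition(trio_ped(), "Population", "Bv")
  row <- p$Bv[p$Bv$id == "83134", ]
  expect_equal(row$Bv_pa, 10.68, tolerance = 1e-12)
  expect_equal(row$Bv_w, -0.26, tolerance = 1e-9)
  expect_equal(row$Bv_Pop1, 4.34, tolerance = 1e-9)
  expect_equal(row$Bv_Pop2, 6.08, tolerance = 1e-12)
  # founders: whole breeding value in w and in the own-path column
  f1 <- p$Bv[p$Bv$id == "75165", ]
  expect_equal(f1$Bv_pa, 0)
  expect_equal(f1$Bv_w, 9.20)
  expect_equal(f1$Bv_Pop1, 9.20)
  expect_equal(f1$Bv_Pop2, 0)
  expect_identical(p$info$lP, c("Pop1", "Pop2"))
})

test_that("decomposition and conservation hold on random pedigrees", {
  for (mode in c("sire-dam", "sire-mgs")) {
    for (seed in 1:3) {
      ped <- generate_random_pedigree(300, n_paths = 3, n_traits = 2,
                                      seed = seed, parent_mode = mode)
      p <- partition(ped)
      for (tr in c("bv1", "bv2")) {
        bv <- p[[tr]][[tr]]
        scale <- pmax(abs(bv), 1)
        expect_lt(max(abs(p[[tr]][[paste0(tr, "_pa")]] +
                            p[[tr]][[paste0(tr, "_w")]] - bv) / scale), 1e-9)
        expect_lt(max(abs(rowSums(part_matrix(p, tr)) - bv) / scale), 1e-9)
      }
    }
  }
})

test_that("founders satisfy w = bv and whole-value credit after rebasing", {
  ped <- generate_random_pedigree(200, n_paths = 3, seed = 4)
  reb <- set_base(ped, ped$time >= 2)
  p <- partition(reb)
  founders <- is.na(reb$sire) & is.na(reb$dam)
  expect_gt(sum(founders), 0)
  expect_equal(p$bv1$bv1_w[founders], reb$bv1[founders])
  pm <- part_matrix(p, "bv1")
  own <- pm[cbind(which(founders), match(reb$path[founders], p$info$lP))]
  expect_equal(own, reb$bv1[founders])
})

test_that("a single path collapses the partition onto the breeding value", {
  ped <- generate_random_pedigree(100, n_paths = 1, seed = 5)
  p <- partition(ped)
  expect_equal(p$bv1$bv1_P1, ped$bv1)
})

test_that("recursive and gene-flow-matrix routes agree", {
  for (mode in c("sire-dam", "sire-mgs")) {
    ped <- generate_random_pedigree(200, n_paths = 3, n_traits = 2,
                                    seed = 6, parent_mode = mode)
    p <- partition(ped)
    o <- partition_matrix_oracle(ped)
    for (tr in c("bv1", "bv2")) {
      expect_lt(max(abs(part_matrix(p, tr) - part_matrix(o, tr))), 1e-9)
      expect_lt(max(abs(p[[tr]][[paste0(tr, "_w")]] -
                          o[[tr]][[paste0(tr, "_w")]])), 1e-9)
    }
  }
})

test_that("the explicit gene-flow matrix has the expected structure", {
  ped <- trio_ped()
  gf <- gene_flow_matrix(ped, "Population")
  expect_equal(diag(gf$T), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(gf$T[upper.tri(gf$T)] == 0))
  expect_equal(gf$T["83134", "75165"], 0.5)
  expect_equal(Reduce(`+`, gf$path_blocks), gf$T)
  # founders only: T is the identity
  fo <- ped_table(data.frame(id = c("a", "b"), sire = NA_character_,
                             dam = NA_character_, time = 0L,
                             path = c("X", "Y"), bv = c(1, 2)))
  expect_equal(gene_flow_matrix(fo, "path")$T, diag(2), ignore_attr = TRUE)
  expect_error(gene_flow_matrix(ped, "Population", max_n = 2), "too large")
  expect_error(partition_matrix_oracle(ped, "Population", "Bv", max_n = 2),
               "partition\\(\\)")
})

test_that("sire-mgs mode uses half and quarter parental expectations", {
  ped <- ped_table(data.frame(
    id = c("S", "G", "O"), sire = c(NA, NA, "S"), dam = c(NA, NA, "G"),
    time = c(0, 0, 1), path = c("A", "B", "A"), bv = c(2.0, 4.0, 3.0)),
    parent_mode = "sire-mgs")
  p <- partition(ped, "path", "bv")
  row <- p$bv[p$bv$id == "O", ]
  expect_equal(row$bv_pa, 0.5 * 2.0 + 0.25 * 4.0)  # 2.0
  expect_equal(row$bv_w, 3.0 - 2.0)
  # sire half to path A, mgs quarter to path B, w to own path A
  expect_equal(row$bv_A, 0.5 * 2.0 + 1.0)
  expect_equal(row$bv_B, 0.25 * 4.0)
  expect_equal(row$bv_A + row$bv_B, row$bv)
})

test_that("traits are partitioned independently in a joint pass", {
  ped <- generate_random_pedigree(150, n_paths = 2, n_traits = 2, seed = 8)
  joint <- partition(ped, "path", c("bv1", "bv2"))
  solo1 <- partition(ped, "path", "bv1")
  solo2 <- partition(ped, "path", "bv2")
  expect_equal(part_matrix(joint, "bv1"), part_matrix(solo1, "bv1"))
  expect_equal(part_matrix(joint, "bv2"), part_matrix(solo2, "bv2"))
})

test_that("relabelling paths permutes partition columns and nothing else", {
  ped <- generate_random_pedigree(120, n_paths = 3, seed = 10)
  p1 <- partition(ped)
  ren <- ped
  ren$path <- c(P1 = "Zebra", P2 = "Alpha", P3 = "Mid")[ren$path]
  p2 <- partition(ren)
  expect_identical(p2$info$lP, c("Alpha", "Mid", "Zebra"))
  expect_equal(p2$bv1$bv1_Zebra, p1$bv1$bv1_P1)
  expect_equal(p2$bv1$bv1_Alpha, p1$bv1$bv1_P2)
  expect_equal(p2$bv1$bv1_Mid, p1$bv1$bv1_P3)
  expect_equal(p2$bv1$bv1_w, p1$bv1$bv1_w)
})

test_that("missing path labels error by default and bucket when lenient", {
  ped <- trio_ped()
  ped$Population[2] <- NA
  expect_error(partition(ped, "Population", "Bv"), "missing path label")
  expect_warning(p <- partition(ped, "Population", "Bv", strict = FALSE),
                 "Unknown")
  expect_true("Unknown" %in% p$info$lP)
  expect_equal(p$Bv$Bv_Unknown[p$Bv$id == "83134"], 6.08)
  expect_length(p$info$warn, 1L)
})

test_that("long-term contributions are unit fractions crediting ancestry", {
  trio <- ped_table(data.frame(
    id = c("S", "D", "O"), sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
    time = c(0, 0, 1), path = c("X", "Y", "X")))
  ltc <- long_term_contributions(trio, "path")
  row <- ltc$contribution[ltc$contribution$id == "O", ]
  expect_equal(row$contribution_pa, 1)
  expect_equal(row$contribution_w, 0)
  expect_equal(row$contribution_X, 0.5)
  expect_equal(row$contribution_Y, 0.5)
  for (mode in c("sire-dam", "sire-mgs")) {
    ped <- generate_random_pedigree(200, n_paths = 3, seed = 11,
                                    parent_mode = mode)
    pm <- part_matrix(long_term_contributions(ped, "path"), "contribution")
    expect_true(all(pm >= -1e-12 & pm <= 1 + 1e-12))
    expect_equal(unname(rowSums(pm)), rep(1, nrow(pm)))
  }
})

test_that("streaming group summarization equals the two-step route", {
  ped <- generate_random_pedigree(500, n_paths = 3, n_traits = 2, seed = 12)
  one <- partition_and_summarize(ped, by = "time")
  two <- summarize_partition(partition(ped), by = "time")
  for (tr in c("bv1", "bv2")) {
    expect_identical(one[[tr]]$time, two[[tr]]$time)
    expect_identical(one[[tr]]$N, two[[tr]]$N)
    expect_lt(max(abs(as.matrix(one[[tr]][, -1]) -
                        as.matrix(two[[tr]][, -1]))), 1e-12)
  }
  # grouping by id gives back the per-individual partitions
  byid <- partition_and_summarize(ped, by = "id")
  p <- partition(ped)
  m <- match(byid$bv1$id, p$bv1$id)
  expect_equal(as.matrix(byid$bv1[, p$info$lP]),
               part_matrix(p, "bv1")[m, ], ignore_attr = TRUE)
  # the published trio under a constant grouping column
  trio <- trio_ped()
  trio$all <- "all"
  sm <- partition_and_summarize(trio, "Population", "Bv", by = "all")
  expect_identical(sm$Bv$N, 3L)
  expect_equal(sm$Bv$Sum, mean(c(9.20, 12.16, 10.42)))
})

test_that("unsorted input is handled and output keeps input row order", {
  ped <- generate_random_pedigree(60, n_paths = 2, seed = 13)
  shuf <- ped[rev(seq_len(nrow(ped))), ]
  p <- partition(shuf)
  expect_identical(p$bv1$id, shuf$id)
  ps <- partition(ped)
  m <- match(ped$id, shuf$id)
  expect_equal(part_matrix(p, "bv1")[m, ], part_matrix(ps, "bv1"))
})
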