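test_that("attentionMass averages received attention correctly", {
  # hand-set 3x3 attention matrices (rows on the simplex)
  A1 <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0.2, 0.3, 0.5))
  A2 <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 0, 1))
  expected <- (colMeans(A1) + colMeans(A2)) / 2
  # manual arithmetic for the first ROI: (mean(1,.5,.2) + mean(0,0,0)) / 2
  expect_equal(expected[1], (1.7 / 3) / 2)
  got <- attentionMass(list(A1, A2))
  expect_equal(got, expected)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  # uniform attention -> equal ROI weights
  U <- matrix(1 / 4, 4, 4)
  expect_equal(attentionMass(list(U, U)), rep(0.25, 4))
  # single-node graph: the node carries all the mass
  expect_equal(attentionMass(list(matrix(1, 1, 1))), 1)
})

test_that("roiAttention refuses untrained models and averages subjects", {
  cd <- tinyCohortData(n_per_group = 3, seed = 91, n_timepoints = 40)
  model <- initModel(c(tA = 8L, tB = 10L),
                     satConfig(hidden_dim = 8, n_heads = 2, n_layers = 2),
                     fusion_dim = 4, clf_hidden = 4, seed = 4)
  expect_error(roiAttention(model, cd$data, "tA"), "untrained")
  tm <- trainModel(model, cd$data,
                   config = trainConfig(epochs = 1, outer_folds = 2),
                   seed = 6)
  rep <- roiAttention(tm, cd$data, "tA")
  expect_s3_class(rep, "attentionReport")
  expect_length(rep$roi_weights, 8)
  expect_true(all(rep$roi_weights >= 0))
  expect_equal(sum(rep$roi_weights), 1, tolerance = 1e-9)
  # averaging over one subject equals that subject's own attention mass
  rep1 <- roiAttention(tm, cd$data, "tA", idx = 2L)
  fo <- atlasfuse:::.forwardSubject(tm, lapply(cd$data$graphs, `[[`, 2L),
                                    collect = TRUE)
  expect_equal(rep1$roi_weights, attentionMass(fo$attn$tA))
  # multi-subject report is the mean of single-subject reports
  rep12 <- roiAttention(tm, cd$data, "tA", idx = c(1L, 2L))
  repA <- roiAttention(tm, cd$data, "tA", idx = 1L)
  expect_equal(rep12$roi_weights, (repA$roi_weights + rep1$roi_weights) / 2)
})

test_that("topROIs ranks deterministically with index tie-breaks", {
  w <- c(0.3, 0.5, 0.3, 0.1)
  top <- topROIs(w, 4)
  expect_identical(top$roi_index, c(2L, 1L, 3L, 4L))  # tie 1 vs 3 -> lower
  expect_identical(top$rank, 1:4)
  expect_identical(topROIs(w, 2)$roi_index, c(2L, 1L))
  expect_error(topROIs(w, 5), "exceeds")
  labelled <- topROIs(w, 2, labels = c("a", "b", "c", "d"))
  expect_identical(labelled$roi_label, c("b", "a"))
})

test_that("bhFDR matches the literal step-up rule and an oracle sweep", {
  expect_identical(bhFDR(numeric(0)), numeric(0))
  expect_equal(bhFDR(0.037), 0.037)                 # single p: q = p
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(rep(1, 7)), rep(1, 7))
  expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
  set.seed(99)
  for (r in 1:1000) {
    m <- sample(1:100, 1)
    p <- round(runif(m), sample(1:3, 1))  # rounding induces ties
    expect_equal(bhFDR(p), bhOracle(p))
  }
})

test_that("discriminativeEdges finds planted effects and nothing else", {
  set.seed(17)
  n <- 20
  mkFC <- function(edgeVals) {
    m <- diag(10)
    m[upper.tri(m)] <- edgeVals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  # identical groups (copied subjects): zero significant edges
  base <- lapply(1:n, function(i) mkFC(rnorm(45, 0, 0.1)))
  es0 <- discriminativeEdges(c(base, base), rep(c(0, 1), each = n), 1:10)
  expect_equal(nrow(es0), 45)                       # C(10, 2) pairs tested
  expect_false(any(es0$significant))
  # one edge shifted by 5 pooled SDs in cases
  cases <- lapply(1:n, function(i) {
    v <- rnorm(45, 0, 0.1); v[1] <- v[1] + 0.5
    mkFC(v)
  })
  controls <- lapply(1:n, function(i) mkFC(rnorm(45, 0, 0.1)))
  es <- discriminativeEdges(c(controls, cases), rep(c(0, 1), each = n), 1:10)
  shifted <- es$roi_i == 1 & es$roi_j == 2          # first upper-tri slot
  expect_true(es$significant[shifted])
  expect_lte(sum(es$significant & !shifted), 2)     # BH keeps the rest tame
  # Welch t and p agree with stats::t.test on a random edge (pair 3-7)
  ev <- vapply(c(controls, cases), function(m) m[3, 7], 0)
  tt <- t.test(ev[21:40], ev[1:20])
  row <- which(es$roi_i == 3 & es$roi_j == 7)
  expect_equal(es$t[row], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(es$p[row], tt$p.value, tolerance = 1e-10)
  # zero-variance edge in both groups -> p = 1, flagged
  flat <- lapply(1:6, function(i) mkFC(c(0.5, rnorm(44, 0, 0.1))))
  esf <- discriminativeEdges(flat, rep(c(0, 1), 3), 1:10)
  expect_true(esf$degenerate[1])
  expect_equal(esf$p[1], 1)
  expect_error(discriminativeEdges(base[1:3], c(0, 0, 1), 1:10),
               "2 subjects per group")
})

test_that("crossAtlasOverlap buckets regions by atlas support", {
  map <- rbind(
    data.frame(atlas = "a1", roi_label = paste0("x", 1:4),
               region = c("R1", "R2", "R3", "R4")),
    data.frame(atlas = "a2", roi_label = paste0("y", 1:4),
               region = c("R1", "R2", "R5", "R6")),
    data.frame(atlas = "a3", roi_label = paste0("z", 1:4),
               region = c("R1", "R7", "R8", "R9")))
  # exactly one region (R1) present in all three lists
  ov <- crossAtlasOverlap(list(a1 = c("x1", "x2", "x3"),
                               a2 = c("y1", "y2", "y3"),
                               a3 = c("z1", "z2", "z3")), map)
  expect_identical(ov$buckets[["3"]], "R1")
  expect_identical(ov$buckets[["2"]], "R2")
  expect_setequal(ov$buckets[["1"]], c("R3", "R5", "R7", "R8"))
  expect_equal(nrow(ov$unmatched), 0)
  # identical label sets under an identity-style map -> all three-atlas
  idmap <- do.call(rbind, lapply(c("a1", "a2", "a3"), function(a)
    data.frame(atlas = a, roi_label = c("u", "v"), region = c("u", "v"))))
  ov2 <- crossAtlasOverlap(list(a1 = c("u", "v"), a2 = c("u", "v"),
                                a3 = c("u", "v")), idmap)
  expect_setequal(ov2$buckets[["3"]], c("u", "v"))
  # pairwise-disjoint sets -> all singletons
  ov3 <- crossAtlasOverlap(list(a1 = "x1", a2 = "y3", a3 = "z4"), map)
  expect_equal(sort(ov3$table$n_atlases), c(1L, 1L, 1L))
  # unmapped labels are surfaced, never dropped
  ov4 <- crossAtlasOverlap(list(a1 = c("x1", "mystery")), map)
  expect_identical(ov4$unmatched$roi_label, "mystery")
})

test_that("region maps derive from centroids and from simulation specs", {
  atlA <- atlasSpec("cA", c("p", "q"),
                    centroids = rbind(c(0, 0, 0), c(50, 0, 0)))
  atlB <- atlasSpec("cB", c("r", "s"),
                    centroids = rbind(c(3, 0, 0), c(52, 0, 0)))
  map <- regionMapFromCentroids(list(atlA, atlB), max_dist = 10)
  reg <- setNames(map$region, paste(map$atlas, map$roi_label))
  expect_identical(unname(reg["cA p"]), unname(reg["cB r"]))
  expect_identical(unname(reg["cA q"]), unname(reg["cB s"]))
  expect_false(reg["cA p"] == reg["cA q"])

  spec <- recoverySimSpec(seed = 1)
  smap <- regionMapFromSpec(spec)
  expect_identical(sort(unique(smap$atlas)), c("toy20", "toy34", "toy42"))
  # ROIs sharing a latent source share a region across atlases
  expect_identical(smap$region[smap$atlas == "toy20"][1],
                   smap$region[smap$atlas == "toy42"][1])
})

test_that("attention reports write viewer-friendly CSV", {
  td <- withr::local_tempdir()
  rep <- structure(list(atlas = "tA", roi_weights = c(0.4, 0.1, 0.3, 0.2),
                        n_subjects = 2),
                   class = "attentionReport")
  atl <- atlasSpec("tA", paste0("tA_R", 1:4))
  f <- file.path(td, "attn.csv")
  writeAttentionReport(rep, atl, f)
  df <- utils::read.csv(f)
  expect_identical(df$rank, c(1L, 4L, 2L, 3L))
  expect_identical(df$roi_label, paste0("tA_R", 1:4))
})

test_that("model checkpoints round-trip with a versioned header", {
  td <- withr::local_tempdir()
  model <- initModel(c(tA = 8L),
                     satConfig(hidden_dim = 8, n_heads = 2, n_layers = 1),
                     fusion_dim = 4, clf_hidden = 4, seed = 12)
  f <- file.path(td, "model.ckpt")
  saveModel(model, f)
  m2 <- loadModel(f)
  expect_identical(m2@params, model@params)
  expect_identical(m2@satConfig, model@satConfig)
  saveRDS(list(format = "other"), f)
  expect_error(loadModel(f), "not an atlasfuse checkpoint")
})

test_that("viewer node and edge files carry coordinates and t-values", {
  td <- withr::local_tempdir()
  atl <- atlasSpec("vA", paste0("v", 1:4),
                   centroids = matrix(seq_len(12), 4, 3))
  rep <- structure(list(atlas = "vA", roi_weights = c(0.4, 0.3, 0.2, 0.1),
                        n_subjects = 1),
                   class = "attentionReport")
  edges <- data.frame(roi_i = 1L, roi_j = 3L, t = 4.2, p = 0.001,
                      q = 0.01, significant = TRUE, degenerate = FALSE)
  nf <- file.path(td, "nodes.node"); ef <- file.path(td, "edges.edge")
  writeBrainNetFiles(rep, atl, nf, ef, edges)
  nodes <- utils::read.table(nf)
  expect_equal(nodes$V4, c(0.4, 0.3, 0.2, 0.1))
  expect_identical(nodes$V5, paste0("v", 1:4))
  M <- unname(as.matrix(utils::read.table(ef)))
  expect_equal(M[1, 3], 4.2)
  expect_equal(M[3, 1], 4.2)
  expect_equal(sum(M != 0), 2)
})
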