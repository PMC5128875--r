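# Distance profiles, Pearson similarity, classification, in-register
# scoring, secondary structure, clustering, heat maps, frame averaging.

test_that("long-range pair sets have the enumerated sizes", {
  expect_equal(nrow(ca_pairs(17, 40, 5)), 190)
  expect_equal(nrow(ca_pairs(17, 42, 5)), 231)
  expect_equal(nrow(ca_pairs(1, 5, 5)), 0)
  # brute-force enumeration oracle
  brute <- function(a, b, m) {
    n <- 0
    for (i in a:b) for (j in a:b) if (j - i >= m) n <- n + 1
    n
  }
  expect_equal(nrow(ca_pairs(17, 40)), brute(17, 40, 5))
  expect_equal(nrow(ca_pairs(17, 42)), brute(17, 42, 5))
  expect_true(all(ca_pairs(17, 42)$j - ca_pairs(17, 42)$i >= 5))
})

test_that("distance profiles average chains and respect geometry", {
  # single straight chain at 3.8 A spacing: d(i, j) = 3.8 |i - j|
  ca <- tibble::tibble(index = 1:26, chain = 1L, residue = 17:42,
                       bead = "CA", aa = "A",
                       x = (0:25) * 3.8, y = 0, z = 0)
  p <- distance_profile(ca, c(17, 42))
  expect_equal(p$dist, 3.8 * (p$j - p$i))
  # two translated copies average to the single-chain profile
  ca2 <- ca; ca2$chain <- 2L; ca2$y <- 40
  p2 <- distance_profile(dplyr::bind_rows(ca, ca2), c(17, 42))
  expect_equal(p2$dist, p$dist)
  # random multi-chain structure matches a double-loop recomputation
  u <- make_fibril("S2", 4, jitter = 1, seed = 3)
  p3 <- distance_profile(u, c(17, 40))
  caU <- u[u$bead == "CA", ]
  brute <- vapply(seq_len(nrow(p3)), function(k) {
    mean(vapply(unique(caU$chain), function(ch) {
      a <- caU[caU$chain == ch & caU$residue == p3$i[k], ]
      b <- caU[caU$chain == ch & caU$residue == p3$j[k], ]
      sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(p3$dist, brute, tolerance = 1e-12)
  # missing residues are a named error
  expect_error(distance_profile(ca[ca$residue != 30, ], c(17, 42)),
               class = "fibril_missing_data")
})

test_that("the similarity statistic behaves like a Pearson correlation", {
  u <- distance_profile(make_fibril("U", 4), c(17, 42))
  s <- distance_profile(make_fibril("S1", 4), c(17, 42))
  expect_equal(pearson_similarity(u, u)$r, 1)
  # reflection about the mean gives -1
  refl <- u
  refl$dist <- 2 * mean(u$dist) - u$dist
  expect_equal(pearson_similarity(u, refl)$r, -1)
  # symmetry
  expect_identical(pearson_similarity(u, s)$r, pearson_similarity(s, u)$r)
  # hand-computed three-point example
  pa <- tibble::tibble(i = c(1, 1, 1), j = c(6, 7, 8),
                       dist = c(1, 2, 4))
  pb <- pa; pb$dist <- c(1, 3, 3)
  expect_equal(pearson_similarity(pa, pb)$r, 8 / sqrt(112),
               tolerance = 1e-12)
  expect_equal(round(pearson_similarity(pa, pb)$r, 3), 0.756)
  # zero variance is an explicit error, not a silent 0
  pc <- pa; pc$dist <- c(2, 2, 2)
  expect_error(pearson_similarity(pa, pc),
               class = "fibril_undefined_score")
  # mismatched pair sets refuse to compare
  expect_error(pearson_similarity(u, distance_profile(make_fibril("U", 4),
                                                      c(17, 40))))
})

test_that("similarity is invariant under independent rigid motions", {
  u <- make_fibril("U", 3)
  s <- make_fibril("S3", 3)
  r0 <- pearson_similarity(distance_profile(u), distance_profile(s))$r
  set.seed(8)
  for (k in 1:5) {
    u2 <- fibrildmd:::transform_structure(
      u, rot = fibrildmd:::random_rotation(), shift = rnorm(3, 0, 30))
    s2 <- fibrildmd:::transform_structure(
      s, rot = fibrildmd:::random_rotation(), shift = rnorm(3, 0, 30))
    r1 <- pearson_similarity(distance_profile(u2), distance_profile(s2))$r
    expect_lt(abs(r1 - r0), 1e-12)
  }
})

test_that("similarity degrades monotonically with noise amplitude", {
  u <- make_fibril("U", 4)
  pu <- distance_profile(u)
  mean_r <- vapply(c(0.5, 1, 2, 4), function(amp) {
    mean(vapply(1:20, function(s) {
      pearson_similarity(distance_profile(perturb_structure(u, amp,
                                                            seed = s)),
                         pu)$r
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))
})

test_that("chain clustering equals a reference graph search", {
  # no contacts: all singletons
  coil <- make_coil(4, seed = 2, spacing = 80)
  cl <- cluster_chains(coil)
  expect_equal(attr(cl, "sizes"), rep(1L, 4))
  # A-B-C chain of contacts plus isolated D
  u3 <- make_fibril("U", 3)
  d <- make_fibril("U", 1)
  d$chain <- 4L
  d <- fibrildmd:::transform_structure(d, shift = c(0, 0, 200))
  comb <- dplyr::bind_rows(u3, d)
  comb$index <- seq_len(nrow(comb))
  cl <- cluster_chains(comb)
  expect_equal(attr(cl, "sizes"), c(3L, 1L))
  expect_equal(cl$cluster[cl$chain == 4], 2L)
  # dense random configuration against the BFS oracle
  dense <- perturb_structure(make_fibril("D2", 6), 3, seed = 9)
  cl <- cluster_chains(dense, cutoff = 7, min_contacts = 4)
  ref <- oracle_clusters(dense, 7, 4)
  got <- split(cl$chain, cl$cluster)
  norm <- function(l) unname(lapply(l[order(vapply(l, min, 1))], sort))
  expect_equal(norm(got), norm(ref))
})

test_that("classification recovers generating classes and flags hybrids", {
  lib <- reference_library()
  u <- make_fibril("U", 8, jitter = 0.5, seed = 1)
  lab <- classify_structure(u, lib)
  expect_equal(lab$class, "U")
  # the exact stack is recognised as in-register
  lab0 <- classify_structure(make_fibril("U", 8), lib)
  expect_true(lab0$in_register)
  s2 <- make_fibril("S2", 8, jitter = 0.5, seed = 2)
  expect_equal(classify_structure(s2, lib)$class, "S2")
  bh <- perturb_structure(make_beta_helix(3), 0.5, seed = 3)
  expect_equal(classify_structure(bh, lib)$class, "BH")
  # separated random coils: monomer / small oligomer
  expect_equal(classify_structure(make_coil(3, seed = 4), lib)$class,
               "M+SO")
  # a U tetramer in contact with a BH trimer is a hybrid aggregate
  comb <- compose_u_bh()
  expect_equal(attr(cluster_chains(comb), "sizes")[1], 7L)
  lab <- classify_structure(comb, lib)
  expect_equal(lab$class, "hybrid")
  # empty reference library is a configuration error
  expect_error(classify_structure(u, lib[0, ]),
               class = "fibril_config_error")
})

test_that("tidiers expose similarity and classification results", {
  u <- make_fibril("U", 4)
  lab <- classify_structure(u, reference_library())
  td <- generics::tidy(lab)
  expect_true(all(c("reference", "r", "class") %in% names(td)))
  gl <- generics::glance(lab)
  expect_equal(gl$class, "U")
  sc <- pearson_similarity(distance_profile(u), distance_profile(u),
                           reference_id = "self")
  expect_equal(generics::tidy(sc)$r, 1)
})

test_that("the in-register score separates aligned from shifted stacks", {
  tab <- default_forcefield()
  u <- make_fibril("U", 4)
  expect_equal(as.numeric(in_register_score(u, tab)), 1)
  sh <- make_fibril("U", 4, register_shift = 1)
  expect_equal(as.numeric(in_register_score(sh, tab)), 0)
  expect_gt(attr(in_register_score(sh, tab), "n_hb"), 0)
  # no inter-chain bonds: flagged undefined
  lone <- make_coil(2, seed = 5, spacing = 100)
  sc <- in_register_score(lone, tab)
  expect_true(is.na(sc))
})

test_that("in-register score matches a direct bond count on a mixed stack", {
  tab <- default_forcefield()
  u <- make_fibril("U", 2)
  sh <- make_fibril("U", 2, register_shift = 1)
  sh$chain <- sh$chain + 2L
  sh <- fibrildmd:::transform_structure(sh, shift = c(0, 0, 250))
  comb <- dplyr::bind_rows(u, sh)
  comb$index <- seq_len(nrow(comb))
  topo <- build_peptide(ab1742_sequence(), 4, 17L, tab)
  hb <- assign_hbonds(comb, topo, tab)
  inter <- hb[hb$chain_nh != hb$chain_co, ]
  direct <- mean(inter$res_nh - inter$res_co == 1)
  got <- in_register_score(comb, tab, hbonds = hb)
  expect_equal(as.numeric(got), direct)
  expect_true(direct > 0 && direct < 1)
})

test_that("secondary structure assigns sheets, helices and coils", {
  tab <- default_forcefield()
  # two-chain parallel sheet with a full hydrogen-bond ladder
  sheet <- make_beta_helix(2, twist = 0)
  fr <- secondary_structure_fractions(sheet, tab)
  expect_gte(fr$beta, 0.9)
  expect_equal(fr$alpha + fr$beta + fr$coil, 1)
  # ideal coarse-grained helix: CA on a 2.3 A radius, 1.5 A rise spiral
  th <- (0:25) * 100 * pi / 180
  helix <- tibble::tibble(index = 1:26, chain = 1L, residue = 17:42,
                          bead = "CA", aa = "A",
                          x = 2.3 * cos(th), y = 2.3 * sin(th),
                          z = (0:25) * 1.5)
  fr <- secondary_structure_fractions(
    helix, tab, hbonds = tibble::tibble(nh = integer(0), co = integer(0)))
  expect_gte(fr$alpha, 0.9)
  # a single extended strand without hydrogen bonds is all coil
  lone <- make_beta_helix(2, twist = 0)
  lone <- lone[lone$chain == 1, ]
  attr(lone, "topology") <- NULL
  fr <- secondary_structure_fractions(
    lone, tab, hbonds = tibble::tibble(nh = integer(0), co = integer(0)))
  expect_equal(fr$beta, 0)
})

test_that("population heat maps select trajectory tails and normalize", {
  # 10-frame trajectory with tail 0.30 keeps frames 8, 9, 10
  frames <- tibble::tibble(trajectory = 1, frame = 1:10,
                           r = seq(0.1, 1, by = 0.1), energy = -(1:10))
  hm <- population_heatmap(frames, tail_fraction = 0.30)
  expect_equal(sort(hm$points$frame), 8:10)
  expect_equal(sum(hm$density), 1)
  # identical frames occupy a single bin of density 1
  same <- tibble::tibble(trajectory = 1, frame = 1:5, r = 0.9,
                         energy = -100)
  hm <- population_heatmap(same, tail_fraction = 1)
  expect_equal(max(hm$density), 1)
  expect_equal(sum(hm$density > 0), 1)
  # two synthetic populations recover their mixture weights
  mix <- dplyr::bind_rows(
    tibble::tibble(trajectory = 1, frame = 1:300,
                   r = 0.9 + runif(300, -0.01, 0.01),
                   energy = -150 + runif(300, -1, 1)),
    tibble::tibble(trajectory = 2, frame = 1:100,
                   r = 0.2 + runif(100, -0.01, 0.01),
                   energy = -40 + runif(100, -1, 1)))
  hm <- population_heatmap(mix, tail_fraction = 1,
                           e_breaks = seq(-160, -30, by = 10))
  hi <- hm$points$r > 0.5
  expect_equal(sum(hm$density[hm$r_breaks[-1] > 0.5, ]), 0.75,
               tolerance = 0.01)
  expect_error(population_heatmap(frames, tail_fraction = 0))
})

test_that("frame averaging removes rigid motion and averages noise", {
  u <- make_fibril("U", 2)
  # identical frames: output equals input
  avg <- frame_average(list(u, u, u))
  expect_equal(avg$x, u$x)
  # frames differing by rigid rotations only collapse onto frame 1
  set.seed(3)
  frames <- c(list(u), lapply(1:4, function(k) {
    fibrildmd:::transform_structure(u, rot = fibrildmd:::random_rotation(),
                                    shift = rnorm(3, 0, 10))
  }))
  avg <- frame_average(frames)
  expect_lt(max(abs(avg$x - u$x)), 1e-6)
  expect_lt(max(abs(avg$z - u$z)), 1e-6)
  # iid jitter shrinks roughly as 1/sqrt(n)
  rms_after <- function(n_frames) {
    fr <- lapply(seq_len(n_frames), function(s) {
      perturb_structure(u, 0.5, seed = 100 + s)
    })
    a <- frame_average(fr, align = FALSE)
    sqrt(mean((a$x - u$x)^2 + (a$y - u$y)^2 + (a$z - u$z)^2))
  }
  r4 <- rms_after(4); r16 <- rms_after(16)
  expect_lt(r16, r4 / 1.5)
  # mismatched topologies refuse to average
  expect_error(frame_average(list(u, make_fibril("U", 3))), "mismatched")
})
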