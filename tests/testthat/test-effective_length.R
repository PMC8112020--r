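test_that("fragment-length distributions validate and normalize", {
  expect_error(frag_len_dist(c(0.5, 0.4)), "sums to")
  expect_error(frag_len_dist(c(-0.1, 1.1)), "negative")
  D <- frag_len_dist(c(0.25, 0.75))
  expect_equal(D$max_len, 2L)
  expect_equal(empirical_fld(c(2L, 2L, 2L))$pmf, c(0, 1))
  expect_equal(empirical_fld(c(1L, 2L, 3L))$pmf, rep(1 / 3, 3))
  sm <- empirical_fld(c(1L, 2L, 3L), smooth = 1L)
  expect_equal(sum(sm$pmf), 1)
  expect_error(empirical_fld(integer(0)), "nonempty")
})

test_that("transcript effective length matches the forced examples", {
  expect_equal(transcript_eff_len(point_fld(2L), 5L), 4)
  expect_equal(transcript_eff_len(point_fld(2L), 5L, "classical"), 4)
  # uniform D on 1..l gives (l+1)/2
  for (l in c(4L, 9L, 20L)) {
    expect_equal(transcript_eff_len(unif_fld(1L, l), l), (l + 1) / 2)
  }
})

test_that("window-sum and classical forms agree on random (D, l)", {
  set.seed(21)
  for (i in 1:200) {
    pmf <- stats::rgamma(sample(3:20, 1L), 1)
    D <- frag_len_dist(pmf / sum(pmf))
    l <- sample(1:50, 1L)
    a <- transcript_eff_len(D, l)
    b <- transcript_eff_len(D, l, "classical")
    expect_lt(abs(a - b), 1e-12 * max(1, a))
    # independent double-loop oracle
    br <- 0
    for (j in seq_len(l)) for (k in j:l) br <- br + fld_d_test(D, k - j + 1L)
    expect_equal(a, br, tolerance = 1e-12)
  }
})

test_that("path effective length matches hand examples and the window loop", {
  g <- chain_graph(c(5L, 3L))
  D <- point_fld(2L)
  expect_equal(path_eff_len(g, 2L, D), 4)          # singleton [a], len 5
  g2 <- chain_graph(c(3L, 3L))
  expect_equal(path_eff_len(g2, c(2L, 3L), D), 1)  # junction-straddling
  # closed form vs generic window enumeration on random small paths
  set.seed(22)
  for (i in 1:40) {
    fx <- small_fixture(3000L + i, short_exons = TRUE)
    g <- fx$graph; D <- fx$fld
    aff <- affinity_model(D)
    P <- build_phasing_set(g, D)
    for (p in P$paths) {
      closed <- path_eff_len(g, p, D)
      ex <- p; lens <- g$exon_len[ex]; L <- sum(lens)
      cum <- cumsum(c(0L, lens))
      brute <- 0
      for (j in seq_len(L)) for (k in j:L) {
        fi <- findInterval(j, cum + 1L); li <- findInterval(k, cum + 1L)
        if (fi == 1L && li == length(ex))
          brute <- brute + fld_d_test(D, k - j + 1L)
      }
      expect_equal(closed, brute, tolerance = 1e-12)
    }
  }
})

test_that("path effective length is embedding-independent (no bias)", {
  # [e3] lies on both S-1-2-3-T and S-1-3-T in the chord graph; counting its
  # exactly-mapping windows inside either embedding gives the same value
  g <- chord_graph(c(9L, 6L, 8L))
  D <- unif_fld(2L, 7L)
  per_embedding <- function(ex) {
    lens <- g$exon_len[ex]; L <- sum(lens); cum <- cumsum(c(0L, lens))
    tgt <- which(ex == 4L)
    acc <- 0
    for (j in seq_len(L)) for (k in j:L) {
      fi <- findInterval(j, cum + 1L); li <- findInterval(k, cum + 1L)
      if (fi == tgt && li == tgt) acc <- acc + fld_d_test(D, k - j + 1L)
    }
    acc
  }
  v1 <- per_embedding(c(2L, 3L, 4L))
  v2 <- per_embedding(c(2L, 4L))
  expect_equal(v1, v2)
  expect_equal(path_eff_len(g, 4L, D), v1)
})

test_that("normalization reparameterization holds on random instances", {
  set.seed(23)
  for (i in 1:40) {
    fx <- small_fixture(4000L + i, short_exons = TRUE)
    g <- fx$graph; D <- fx$fld
    P <- build_phasing_set(g, D)
    trs <- enumerate_st_paths(g, 256L)
    ab <- stats::rgamma(length(trs), 1)
    qts <- quantified_transcripts(g, trs, ab)
    lhs <- sum(qts$abundances * transcript_eff_len(D, qts$lengths))
    cp <- true_path_abundances(qts, P)
    rhs <- sum(cp * P$eff_len)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("normalization reparameterization holds with positional bias", {
  set.seed(24)
  g <- chord_graph(c(6L, 5L, 7L))
  pmf <- numeric(6); pmf[2:6] <- c(.1, .3, .3, .2, .1)
  D <- frag_len_dist(pmf)
  trs <- enumerate_st_paths(g, 16L)
  ab <- c(0.6, 0.4)
  qts <- quantified_transcripts(g, trs, ab)
  bias <- reference_bias(g, trs, ab, D,
                         bin_weights = c(0.5, 1, 2, 1, 0.5))
  aff <- affinity_model(D, "positional", bias)
  P <- build_phasing_set(g, D, aff = aff)
  # transcript effective length under the same affinities, by window loop
  lhs <- 0
  for (i in seq_along(trs)) {
    ex <- trs[[i]][-c(1L, length(trs[[i]]))]
    lens <- g$exon_len[ex]; L <- sum(lens); cum <- cumsum(c(0L, lens))
    li_hat <- 0
    for (j in seq_len(L)) for (k in j:L) {
      fi <- findInterval(j, cum + 1L); li <- findInterval(k, cum + 1L)
      p <- ex[fi:li]
      li_hat <- li_hat + positional_affinity(bias, g, p,
                                             j - cum[fi], k - cum[fi])
    }
    lhs <- lhs + ab[i] * li_hat
  }
  cp <- true_path_abundances(qts, P)
  rhs <- sum(cp * P$eff_len)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("positional affinity is the abundance-weighted mean", {
  g <- chord_graph(c(10L, 8L, 12L))
  D <- unif_fld(2L, 6L)
  trs <- enumerate_st_paths(g, 16L)
  b1 <- reference_bias(g, trs[1L], 1, D)
  # single reference transcript: affinity equals its own bias value
  expect_equal(positional_affinity(b1, g, 2L, 1L, 4L),
               spliceflow:::bias_B(b1, 30L, 1L, 4L))
  # weighted means with bin weights chosen to give distinct B values
  bw <- c(2, 1, 1, 1, 4)
  b2 <- reference_bias(g, trs, c(1, 1), D, bin_weights = bw)
  b3 <- reference_bias(g, trs, c(3, 1), D, bin_weights = bw)
  # window late in e3: relative position differs between the two embeddings
  v1 <- spliceflow:::bias_B(b2, 30L, 27L, 30L)  # on S-1-2-3-T (len 30)
  v2 <- spliceflow:::bias_B(b2, 22L, 19L, 22L)  # on S-1-3-T (len 22)
  p <- 4L  # singleton [e3]
  expect_equal(positional_affinity(b2, g, p, 9L, 12L), (v1 + v2) / 2)
  expect_equal(positional_affinity(b3, g, p, 9L, 12L), (3 * v1 + v2) / 4)
  expect_error(positional_affinity(reference_bias(g, trs[2L], 1, D),
                                   g, 3L, 1L, 2L),
               "no reference transcript")
})

test_that("fld TSV round-trips", {
  D <- normal_fld(60, 15, 20L, 120L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fld_tsv(D, f)
  D2 <- read_fld_tsv(f)
  expect_equal(D2$pmf, D$pmf, tolerance = 1e-12)
})
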