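identity_synteny <- function(len, src = "src", tgt = "tgt") {
  synteny_map(data.frame(src_chrom = "chrT", src_start = 0, src_end = len,
                         tgt_chrom = "chrT", tgt_start = 0, tgt_end = len,
                         orientation = "+"),
              source_genome = src, target_genome = tgt)
}

test_that("easy liftover through an identity map is the identity", {
  g <- bin_grid("chrT", 60000, 10000)
  m <- random_toy_map(g, seed = 1)
  out <- liftover_easy(m, identity_synteny(60000), g)
  expect_equal(out$values, m$values, tolerance = 1e-12)
  expect_equal(out$genome, "tgt")
})

test_that("mutant-to-reference easy liftover masks exactly the deletion", {
  g_ref <- bin_grid("chrT", 100000, 10000)
  g_mut <- bin_grid("chrT", 80000, 10000)
  m <- random_toy_map(g_mut, seed = 2)
  m$genome <- "mut"
  syn_back <- invert_synteny(
    deletion_to_synteny(deletion_spec("chrT", 30000, 50000), 100000,
                        source_genome = "ref", target_genome = "mut"))
  out <- liftover_easy(m, syn_back, g_ref)
  expect_equal(which(out$masked), c(4L, 5L))
  # values preserved around the deletion
  expect_equal(out$values[1:3, 1:3], m$values[1:3, 1:3], tolerance = 1e-12)
  expect_equal(out$values[6:10, 6:10], m$values[4:8, 4:8], tolerance = 1e-12)
})

test_that("easy liftover agrees with bp-level enumeration, inverted block included", {
  g6 <- bin_grid("chrT", 60, 10)
  syn <- synteny_map(data.frame(src_chrom = "chrT", src_start = c(0, 30),
                                src_end = c(30, 60), tgt_chrom = "chrT",
                                tgt_start = c(0, 30), tgt_end = c(30, 60),
                                orientation = c("+", "-")),
                     source_genome = "src", target_genome = "tgt")
  m <- random_toy_map(g6, seed = 3)
  out <- liftover_easy(m, syn, g6)
  expect_equal(out$values, oracle_liftover(m$values, syn, g6, g6),
               tolerance = 1e-9)
})

test_that("easy liftover conserves mass and rejects bad inputs", {
  g <- bin_grid("chrT", 200, 10)
  for (s in 1:5) {
    syn <- random_synteny(200, seed = s)
    tgt_len <- max(syn$blocks$tgt_end)
    g_t <- bin_grid("chrT", tgt_len, 10)
    m <- random_toy_map(g, seed = s + 100)
    out <- liftover_easy(m, syn, g_t)
    # mass over mapped source pairs: bp-level oracle total equals output total
    expect_equal(sum(out$values),
                 sum(oracle_liftover(m$values, syn, g, g_t)),
                 tolerance = 1e-9)
    expect_identical(out$values, t(out$values))
  }
  m <- random_toy_map(g, seed = 1)
  expect_error(liftover_easy(m, random_synteny(200, 1), bin_grid("chrT", 200, 20)),
               "bin size mismatch")
  m$genome <- "elsewhere"
  expect_error(liftover_easy(m, random_synteny(200, 1), g),
               "direction mismatch")
})

test_that("balanced liftover: identity synteny, same-side invariance, hand case", {
  n <- 8
  g8 <- bin_grid("chrT", 8000, 1000)
  v <- outer(1:n, 1:n, function(i, j) 8 / (1 + abs(i - j)))
  m <- contact_map(g8, v, normalization = "vc_sqrt", genome = "ref")
  e <- estimate_expected(m)
  # identity: s' == s everywhere
  syn_id <- identity_synteny(8000, "ref", "copy")
  expect_equal(liftover_balanced(m, syn_id, e, g8)$values, v,
               tolerance = 1e-12)
  # deletion of 0-based bins 3-4 (bp [3000, 5000))
  del <- deletion_spec("chrT", 3000, 5000)
  syn <- deletion_to_synteny(del, 8000, source_genome = "ref")
  g_mut <- bin_grid("chrT", 6000, 1000)
  bal <- liftover_balanced(m, syn, e, g_mut)
  # pair (1,6) 0-based moves from s=5 to s'=3: value 8/6 * (8/4)/(8/6) = 2
  expect_equal(bal$values[2, 5], 2)
  # both bins left of the deletion: unchanged
  expect_equal(bal$values[1, 3], v[1, 3])
  expect_equal(bal$values[2, 3], v[2, 3])
  expect_error(liftover_balanced(m, syn, e, bin_grid("chrT", 6000, 500)),
               "bin size mismatch")
  raw <- contact_map(g8, v, genome = "ref")
  expect_error(liftover_balanced(raw, syn, e, g_mut), "normalized")
})

test_that("balanced liftover matches bp-level enumeration on random cases", {
  for (s in 1:6) {
    g <- bin_grid("chrT", 120, 10)
    m <- random_toy_map(g, seed = s)
    e <- estimate_expected(m)
    syn <- random_synteny(120, seed = s, allow_invert = TRUE)
    g_t <- bin_grid("chrT", max(syn$blocks$tgt_end), 10)
    out <- liftover_balanced(m, syn, e, g_t)
    expect_equal(out$values,
                 oracle_liftover(m$values, syn, g, g_t, expected = e$values),
                 tolerance = 1e-9)
  }
})

test_that("reverse balanced liftover inverts the forward one on distance-only maps", {
  n <- 10
  g <- bin_grid("chrT", 10000, 1000)
  v <- outer(1:n, 1:n, function(i, j) 20 / (1 + abs(i - j))^0.8)
  m <- contact_map(g, v, normalization = "vc_sqrt", genome = "ref")
  del <- deletion_spec("chrT", 4000, 6000)
  syn <- deletion_to_synteny(del, 10000, source_genome = "ref")
  g_mut <- bin_grid("chrT", 8000, 1000)
  fwd <- liftover_balanced(m, syn, estimate_expected(m), g_mut)
  fwd$genome <- "deletion"   # relabel for the return trip
  syn_back <- invert_synteny(syn)
  syn_back$source_genome <- "deletion"
  back <- liftover_balanced(fwd, syn_back, estimate_expected(fwd), g)
  # identity holds wherever the mutant-derived profile is defined, i.e. for
  # pairs whose reference separation is within the 8-bin mutant support
  live <- which(!back$masked)
  for (i in live) for (j in live)
    if (abs(i - j) < g_mut$n_bins)
      expect_equal(back$values[i, j], v[i, j], tolerance = 1e-9)
})

test_that("the distance-only null equals P(s') and fixes same-side pairs", {
  n <- 20
  g <- bin_grid("chrT", n * 5000, 5000)
  p_fun <- function(s) 12 / (1 + s)^0.9
  v <- outer(1:n, 1:n, function(i, j) p_fun(abs(i - j)))
  wt <- contact_map(g, v, normalization = "vc_sqrt")
  del <- deletion_spec("chrT", 40000, 60000)   # 0-based bins 8..11
  vstar <- simulate_wt_under_deletion(wt, del)
  expect_equal(which(vstar$masked), 9:12)
  # closed form: every surviving pair carries P(s') at its original spot
  del_bins <- 9:12
  live <- setdiff(1:n, del_bins)
  sprime <- function(i, j) {
    shift <- function(k) k - ifelse(k > max(del_bins), length(del_bins), 0)
    abs(shift(i) - shift(j))
  }
  for (i in live) for (j in live)
    expect_equal(vstar$values[i, j], p_fun(sprime(i, j)), tolerance = 1e-9)
  # zero-length deletion: exact identity
  v0 <- simulate_wt_under_deletion(wt, deletion_spec("chrT", 50000, 50000))
  expect_equal(v0$values, v, tolerance = 1e-12)
  expect_false(any(v0$masked))
})
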