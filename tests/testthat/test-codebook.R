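# Template-library classification: consistency metric, sequential library
# growth, profiles and profile comparison.

test_that("sample consistency matches a brute-force per-sample check", {
  tp <- plant_code_templates(1, seed = 31)[[1]]
  expect_equal(sample_consistency(tp, tp), 1)
  # doubled waveform: agreement exactly where |t_j| <= 0.30 * peak
  w2 <- 2 * tp
  peak <- max(abs(tp))
  manual <- mean(abs(w2 - tp) / peak <= 0.30)
  expect_equal(sample_consistency(w2, tp), manual)
  expect_equal(manual, mean(abs(tp) / peak <= 0.30))
  # inverted biphasic template: only near-zero samples can agree
  neg <- sample_consistency(-tp, tp)
  expect_equal(neg, mean(2 * abs(tp) / peak <= 0.30))
  expect_error(sample_consistency(tp[-1], tp), "length mismatch")
})

test_that("classification is first-match-wins and founds new codes", {
  lib <- neurocode:::new_code_library()
  r1 <- classify_waveform(c(0, 1, 0), lib)
  expect_equal(r1$code_id, "C001")
  expect_true(r1$is_new)
  r2 <- classify_waveform(c(0, 1.01, 0), r1$library)
  expect_equal(r2$code_id, "C001")
  expect_false(r2$is_new)
  # an orthogonal shape founds a second code
  r3 <- classify_waveform(c(1, -1, 1), r2$library)
  expect_equal(r3$code_id, "C002")
  # equivalence with an exhaustive all-template scan oracle
  tp <- plant_code_templates(6, seed = 32)
  lib6 <- lib_from_planted(tp)
  set.seed(33)
  for (i in 1:100) {
    w <- tp[[sample(6, 1)]] * exp(rnorm(1, 0, 0.05)) + rnorm(121, 0, 0.3)
    got <- classify_waveform(w, lib6)$code_id
    cons <- vapply(lib6$codes, function(cd)
      sample_consistency(w, cd$template_uv, lib6$tolerance), 0)
    hit <- which(cons >= lib6$consistency_min)
    want <- if (length(hit)) lib6$codes[[hit[1]]]$code_id else "NEW"
    expect_equal(got, if (want == "NEW") sprintf("C%03d", 7) else want)
  }
})

test_that("same-template members with small noise map to one code", {
  tp <- plant_code_templates(1, seed = 34)
  pw <- planted_waveforms(tp, 100, jitter = 0.02, seed = 34)
  cb <- build_codebook(pw$waveforms)
  expect_equal(length(cb$library$codes), 1)
  expect_equal(cb$library$codes[[1]]$n_members, 100L)
  # template stays the founding waveform
  expect_equal(cb$library$codes[[1]]$template_uv, pw$waveforms[[1]])
  # envelope contains the template
  expect_true(all(cb$library$codes[[1]]$envelope_min <=
                    cb$library$codes[[1]]$template_uv + 1e-12))
  expect_true(all(cb$library$codes[[1]]$envelope_max >=
                    cb$library$codes[[1]]$template_uv - 1e-12))
})

test_that("codebook recovers 10 planted templates at 5% jitter", {
  tp <- plant_code_templates(10, seed = 35)
  pw <- planted_waveforms(tp, 50, jitter = 0.05, seed = 35)
  cb <- build_codebook(pw$waveforms)
  expect_gte(ari(pw$truth, cb$assignments), 0.9)
})

test_that("library growth is deterministic and monotone in its knobs", {
  tp <- plant_code_templates(4, seed = 36)
  pw <- planted_waveforms(tp, 25, jitter = 0.08, noise_sd = 1, seed = 36)
  a <- build_codebook(pw$waveforms)
  b <- build_codebook(pw$waveforms)
  expect_identical(a$assignments, b$assignments)
  # wider tolerance never increases the number of codes
  n_tol <- vapply(c(0.1, 0.2, 0.3, 0.45, 0.6), function(tol)
    length(build_codebook(pw$waveforms, tolerance = tol)$library$codes), 0L)
  expect_true(all(diff(n_tol) <= 0))
  # stricter consistency requirement never decreases the number of codes
  n_con <- vapply(c(0.7, 0.8, 0.9, 0.95), function(cm)
    length(build_codebook(pw$waveforms, consistency_min = cm)$library$codes), 0L)
  expect_true(all(diff(n_con) >= 0))
})

test_that("code profiles normalize, rank, and compare correctly", {
  pr <- code_profile(c("A", "A", "B"))
  expect_equal(unname(pr$frequency), c(2 / 3, 1 / 3))
  expect_equal(pr$top, c("A", "B"))
  expect_equal(code_profile(c("A", "A", "B"), top_k = 1)$top, "A")
  expect_warning(code_profile(c("A", "B"), top_k = 5), "top_k")
  expect_equal(sum(pr$frequency), 1)
  # uniform corpus: each frequency within binomial CI
  set.seed(37)
  ass <- sample(c("A", "B", "C", "D"), 1e4, TRUE)
  pru <- code_profile(ass)
  expect_true(all(abs(pru$frequency - 0.25) < 0.02))
  # identical profiles: zero deltas and zero chi-square
  cmp0 <- compare_profiles(pr, pr)
  expect_true(all(cmp0$delta == 0))
  expect_equal(cmp0$chi_sq, 0)
  # disjoint single-code profiles: |delta| = 1 for each code
  cmp1 <- compare_profiles(code_profile(rep("A", 5)),
                           code_profile(rep("B", 5)))
  expect_equal(sort(abs(unname(cmp1$delta))), c(1, 1))
  expect_equal(sum(cmp1$delta), 0)
  # shifted distributions are detected at n = 5000
  set.seed(38)
  a <- code_profile(sample(c("A", "B", "C"), 5000, TRUE,
                           prob = c(0.5, 0.3, 0.2)))
  b <- code_profile(sample(c("A", "B", "C"), 5000, TRUE,
                           prob = c(0.3, 0.5, 0.2)))
  expect_lt(compare_profiles(a, b)$p_value, 0.01)
  expect_error(compare_profiles(structure(list(total_events = 0), class = "code_profile"), pr),
               "zero-total")
})
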