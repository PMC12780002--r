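# Sequence generator: encoding round trip, analytic gradients vs finite
# differences, training on deterministic corpora, controlled generation,
# fidelity validation, stimulus rendering.

test_that("event encoding inverts exactly", {
  s <- data.frame(code_id = c("B", "A", "B", "C"),
                  interval_ms = c(5, 12.5, 3.25, 8))
  class(s) <- c("event_sequence", "data.frame")
  enc <- encode_events(list(s))
  expect_equal(enc$code_ids, c("A", "B", "C"))
  back <- decode_events(enc)[[1]]
  expect_equal(back$code_id, s$code_id)
  expect_equal(back$interval_ms, s$interval_ms)
  # one-event sequence and alphabet width
  s1 <- s[1, ]
  enc1 <- encode_events(list(s1), code_ids = c("A", "B", "C", "D", "E"))
  expect_equal(length(enc1$sequences[[1]]$type), 1)
  expect_equal(length(enc1$code_ids), 5)
  expect_error(encode_events(list(s), code_ids = c("A", "B")), "unknown")
})

test_that("analytic gradients match finite differences for both cells", {
  ncd <- asNamespace("neurocode")
  for (cell in c("lstm", "gru")) {
    set.seed(50)
    K <- 3; H <- 4; T_ <- 3; B <- 2; nl <- 2
    params <- ncd$init_params(K + 1, H, nl, K, cell, seed = 7)
    xt <- lapply(1:T_, function(t) matrix(rnorm((K + 1) * B), K + 1, B))
    ty <- matrix(sample(1:K, T_ * B, TRUE), T_, B)
    iv <- matrix(abs(rnorm(T_ * B)), T_, B)
    res <- ncd$seq_net_loss(params, xt, ty, iv, H, nl, cell, w_int = 0.7)
    g_an <- ncd$flatten_params(list(
      layers = lapply(res$grads$layers, function(l)
        list(W = l$dW, U = l$dU, b = l$db)),
      Wy = res$grads$Wy, by = res$grads$by,
      Wr = res$grads$Wr, br = res$grads$br))
    v0 <- ncd$flatten_params(params)
    eps <- 1e-6
    idx <- sort(sample(length(v0), 40))
    g_num <- vapply(idx, function(j) {
      vp <- v0; vp[j] <- vp[j] + eps
      vm <- v0; vm[j] <- vm[j] - eps
      lp <- ncd$seq_net_loss(ncd$relist_params(vp, params), xt, ty, iv,
                             H, nl, cell, 0.7, want_grads = FALSE)$loss
      lm <- ncd$seq_net_loss(ncd$relist_params(vm, params), xt, ty, iv,
                             H, nl, cell, 0.7, want_grads = FALSE)$loss
      (lp - lm) / (2 * eps)
    }, 0)
    rel <- abs(g_num - g_an[idx]) / pmax(abs(g_num) + abs(g_an[idx]), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("the model learns a deterministic alternating corpus", {
  s <- data.frame(code_id = rep(c("A", "B"), 150), interval_ms = 10)
  class(s) <- c("event_sequence", "data.frame")
  cfg <- seq_model_config(hidden_units = 16, max_epochs = 30, window = 8,
                          stride = 2, batch_size = 16, seed = 3,
                          patience = 10)
  m <- train_seq_model(list(s), cfg)
  # training log records both loss branches per epoch
  expect_true(all(c("train_type_loss", "train_interval_loss", "val_loss")
                  %in% names(m$log)))
  # walk the sequence and score next-type predictions
  ncd <- asNamespace("neurocode")
  st <- ncd$seq_model_state0(m)
  enc <- encode_events(list(s), m$code_ids, m$interval_scale_ms)
  ty <- enc$sequences[[1]]$type; iv <- enc$sequences[[1]]$interval
  ok <- 0; last <- NULL
  for (t in 1:(length(ty) - 1)) {
    r <- ncd$seq_model_step(m, c(as.numeric(1:2 == ty[t]), iv[t]), st)
    st <- r$state
    ok <- ok + (which.max(r$logits) == ty[t + 1])
    last <- r
  }
  expect_gte(ok / (length(ty) - 1), 0.99)
  # constant-interval corpus: interval predictions within 5%
  expect_lt(abs(last$interval_norm * m$interval_scale_ms - 10) / 10, 0.05)
  # determinism: same config trains to identical parameters
  m2 <- train_seq_model(list(s), cfg)
  expect_identical(m$params, m2$params)
  expect_error(train_seq_model(list(), cfg), "corpus")
})

test_that("temperature -> 0 reproduces deterministic alternation", {
  s <- data.frame(code_id = rep(c("A", "B"), 150), interval_ms = 10)
  class(s) <- c("event_sequence", "data.frame")
  m <- train_seq_model(list(s), seq_model_config(hidden_units = 16,
                                                 max_epochs = 30, window = 8,
                                                 stride = 2, batch_size = 16,
                                                 seed = 3, patience = 10))
  ctl <- gen_control(min_common_occurrences = 25, temperature = 1e-9,
                     beta = 0)
  g <- generate_sequence(m, s[1:4, ], ctl, seed = 1)
  expect_true(all(g$code_id == rep_len(c("A", "B"), nrow(g)) |
                    g$code_id == rep_len(c("B", "A"), nrow(g))))
  # same model and seed: identical sequences
  g2 <- generate_sequence(m, s[1:4, ], ctl, seed = 1)
  expect_identical(g$code_id, g2$code_id)
  expect_identical(g$interval_ms, g2$interval_ms)
  expect_true(all(g$interval_ms > 0))
})

test_that("generation satisfies the common-code occurrence quota", {
  p <- c(A = 0.5, B = 0.3, C = 0.2)
  corpus <- synth_event_corpus(p, 600, seed = 51)
  m <- train_seq_model(corpus, seq_model_config(hidden_units = 16,
                                                max_epochs = 5, window = 8,
                                                stride = 4, batch_size = 16,
                                                seed = 51))
  ctl <- gen_control(min_common_occurrences = 70, common_k = 3)
  g <- generate_sequence(m, corpus[[1]][1:5, ], ctl, seed = 2)
  expect_false(attr(g, "capped"))
  counts <- table(factor(g$code_id, levels = attr(g, "common_codes")))
  expect_true(all(counts >= 70))
  # a tiny cap flags instead of erroring
  gcap <- generate_sequence(m, corpus[[1]][1:5, ],
                            gen_control(min_common_occurrences = 70,
                                        max_length = 20), seed = 2)
  expect_true(attr(gcap, "capped"))
})

test_that("fidelity validation responds to matched and shifted corpora", {
  p <- c(A = 0.4, B = 0.35, C = 0.25)
  a <- synth_event_corpus(p, 2000, seed = 52)[[1]]
  # identical sample: both statistics exactly zero
  v0 <- validate_generated(a, a)
  expect_equal(v0$chi_sq, 0)
  expect_equal(v0$ks_stat, 0)
  expect_true(v0$pass)
  # same-distribution draw: K-S should not reject
  b <- synth_event_corpus(p, 2000, seed = 53)[[1]]
  vb <- validate_generated(a, list(b))
  expect_gt(vb$ks_p, 0.001)
  # +50% interval shift: K-S rejects hard
  sh <- a; sh$interval_ms <- sh$interval_ms * 1.5
  expect_lt(validate_generated(sh, list(a))$ks_p, 0.01)
  # alphabet mismatch warns and unions
  d <- a; d$code_id[1] <- "ZZZ"
  expect_warning(validate_generated(d, list(a)), "alphabet")
})

test_that("rendered stimuli close the detect/classify loop exactly", {
  fs <- 30000
  tp <- plant_code_templates(5, rate = fs, window_ms = 4, seed = 54)
  lib <- lib_from_planted(tp)
  # single event renders exactly its template
  one <- data.frame(code_id = "P01", interval_ms = 10)
  class(one) <- c("event_sequence", "data.frame")
  stim1 <- render_stimulus(one, lib, fs)
  tr1 <- as_uv(stim1)[1, ]
  expect_equal(max(abs(tr1)), max(abs(tp$P01)), tolerance = 0.01)
  # empty sequence: zero-length trace
  e0 <- one[0, ]
  expect_equal(ncol(render_stimulus(e0, lib, fs)$samples), 0)
  expect_error(render_stimulus(data.frame(code_id = "XX", interval_ms = 5),
                               lib, fs), "not in library")
  # round trip across random sequences
  set.seed(55)
  for (r in 1:25) {
    n <- sample(4:10, 1)
    ev <- data.frame(code_id = sample(names(tp), n, TRUE),
                     interval_ms = sample(8:25, n, TRUE) * 1.0)
    class(ev) <- c("event_sequence", "data.frame")
    tr <- as_uv(render_stimulus(ev, lib, fs))[1, ]
    det <- detect_peaks(tr, 10, fs, refractory_ms = 4.5)
    wfs <- suppressWarnings(extract_waveforms(tr, det, fs, window_ms = 4))
    ids <- vapply(wfs, function(w) classify_waveform(w, lib)$code_id, "")
    tw <- vapply(wfs, `[[`, 0, "time_s")
    expect_equal(ids, ev$code_id)
    expect_equal(diff(tw) * 1000, ev$interval_ms[-n], tolerance = 1e-6)
  }
})
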