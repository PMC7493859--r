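test_that("default hybrid network reproduces the reference structure exactly", {
  m <- build_corenup(model_config(), seed = 1)
  s <- count_parameters(m)
  expect_equal(unname(s$path_totals),
               c(1050, 20200, 25050, 2017241),
               ignore_attr = TRUE)
  expect_equal(names(s$path_totals),
               c("feature_extraction", "lstm_path", "conv_path", "dense_path"))
  expect_equal(s$grand_total, 2063541)
  expect_equal(m$shapes$conv1, 147L)
  expect_equal(m$shapes$pool1, 73L)
  expect_equal(m$shapes$lstm, 73L)
  expect_equal(m$shapes$pool2, 36L)
  expect_equal(m$shapes$flat_lstm, 3650L)
  expect_equal(m$shapes$flat_conv, 1800L)
  expect_equal(m$shapes$concat, 5450L)
  # dense path decomposition: 5450*370 + 370 then 370 + 1
  expect_equal(s$layers$params[s$layers$layer == "Dense"], c(2016870, 371))
})

test_that("parameter enumeration equals closed-form counts on random configs", {
  set.seed(20)
  for (rep in 1:6) {
    cfg <- model_config(input_length = sample(24:60, 1),
                        conv1_filters = sample(2:8, 1),
                        conv1_kernel = sample(2:6, 1),
                        lstm_units = sample(2:8, 1),
                        conv2_filters = sample(2:8, 1),
                        conv2_kernel = sample(2:7, 1),
                        dense_units = sample(3:12, 1))
    for (arch in c("corenup", "convnet", "lstm")) {
      m <- nucnet:::build_model(arch, cfg, seed = rep)
      s <- count_parameters(m)
      expected <- count_conv(cfg$conv1_kernel, 4, cfg$conv1_filters) +
        count_dense(m$shapes$concat, cfg$dense_units) +
        count_dense(cfg$dense_units, 1)
      if (arch %in% c("corenup", "lstm")) {
        expected <- expected + count_lstm(cfg$lstm_units, cfg$conv1_filters)
      }
      if (arch %in% c("corenup", "convnet")) {
        expected <- expected +
          count_conv(cfg$conv2_kernel, cfg$conv1_filters, cfg$conv2_filters)
      }
      expect_equal(s$grand_total, expected, info = arch)
      # enumeration really enumerates: totals equal summed array lengths
      expect_equal(s$grand_total, sum(lengths(m$params)))
    }
  }
})

test_that("single-filter first layer has kernel*channels + 1 parameters", {
  cfg <- tiny_model_config()
  cfg$conv1_filters <- 1L; cfg$conv1_kernel <- 3L
  m <- build_corenup(cfg, seed = 2)
  s <- count_parameters(m)
  first <- s$layers$params[s$layers$layer == "Conv1D"][1]
  expect_equal(first, 13)  # 3*4*1 + 1
  expect_equal(first, length(m$params$conv1_W) + length(m$params$conv1_b))
})

test_that("LSTM parameter count follows 4(ud + u^2 + u)", {
  cfg <- tiny_model_config()
  cfg$conv1_filters <- 50L; cfg$lstm_units <- 50L
  m <- build_lstm_baseline(cfg, seed = 1)
  lstm_total <- length(m$params$lstm_W) + length(m$params$lstm_U) +
    length(m$params$lstm_b)
  expect_equal(lstm_total, 20200)

  cfg$conv1_filters <- 1L; cfg$lstm_units <- 1L
  m1 <- build_lstm_baseline(cfg, seed = 1)
  expect_equal(length(m1$params$lstm_W) + length(m1$params$lstm_U) +
                 length(m1$params$lstm_b), 12)  # 4(1 + 1 + 1)
})

test_that("the recurrent baseline is the hybrid minus its conv path", {
  full <- count_parameters(build_corenup(model_config(), seed = 1))
  rec <- count_parameters(build_lstm_baseline(model_config(), seed = 1))
  # removing the conv path drops its 25050 weights and shrinks the first
  # dense layer input from 5450 to 3650 (1800 * 370 fewer weights)
  expect_equal(rec$grand_total, full$grand_total - 25050 - 1800 * 370)
})

test_that("doubling convolution filters strictly increases the total", {
  cfg <- tiny_model_config()
  base <- count_parameters(build_convnet_baseline(cfg, seed = 1))$grand_total
  cfg2 <- cfg; cfg2$conv1_filters <- cfg$conv1_filters * 2L
  expect_gt(count_parameters(build_convnet_baseline(cfg2, seed = 1))$grand_total,
            base)
})

test_that("degenerate pooling configurations are rejected at build time", {
  expect_error(build_corenup(model_config(input_length = 1)), "pooling")
  expect_error(model_config(conv1_filters = 0))
})

test_that("first-layer pre-activations match the receptive-field sum", {
  # single neuron, single channel, length-8 input; interior positions only
  set.seed(31)
  x <- rnorm(8)
  w_by_u <- rnorm(3)                      # w_{-1}, w_0, w_1 -> n = 1
  # tap t of the implementation multiplies x_{k + t - n - 1}, i.e. tap order
  # is the receptive field reversed in u
  W <- matrix(rev(w_by_u), ncol = 1)
  X <- array(x, dim = c(1, 8, 1))
  out <- nucnet:::conv1d_forward(X, W, b = 0, kernel = 3L)$out
  expect_equal(out[1, 2:7, 1],
               conv_receptive_field_oracle(x, w_by_u),
               tolerance = 1e-6)
})

test_that("LSTM hidden states match the gate equations step by step", {
  set.seed(32)
  u <- 3L; d <- 2L; T_ <- 3L
  per_gate <- function() matrix(rnorm(u * d, sd = 0.5), u, d)
  rec <- function() matrix(rnorm(u * u, sd = 0.5), u, u)
  Wf <- per_gate(); Wi <- per_gate(); Wo <- per_gate(); Wc <- per_gate()
  Uf <- rec(); Ui <- rec(); Uo <- rec(); Uc <- rec()
  bf <- matrix(rnorm(u), u, 1); bi <- matrix(rnorm(u), u, 1)
  bo <- matrix(rnorm(u), u, 1); bc <- matrix(rnorm(u), u, 1)
  x_steps <- lapply(1:T_, function(i) rnorm(d))

  H_oracle <- lstm_gate_oracle(x_steps, Wf, Wi, Wo, Wc, Uf, Ui, Uo, Uc,
                               bf, bi, bo, bc)

  # pack into the implementation's [i | f | g | o] column-block layout
  W <- cbind(t(Wi), t(Wf), t(Wc), t(Wo))
  U <- cbind(t(Ui), t(Uf), t(Uc), t(Uo))
  b <- c(bi, bf, bc, bo)
  X <- array(0, dim = c(1, T_, d))
  for (t in 1:T_) X[1, t, ] <- x_steps[[t]]
  H <- nucnet:::lstm_forward(X, W, U, b)$out
  expect_equal(matrix(H[1, , ], T_, u), H_oracle, tolerance = 1e-6)
})

test_that("prediction is deterministic, bounded and batch-invariant", {
  cfg <- tiny_model_config()
  m <- build_corenup(cfg, seed = 3)
  seqs <- random_seqs(33, 24)
  X <- one_hot_encode(seqs)
  p_all <- predict_network(m, X, batch_size = 32)
  expect_true(all(p_all >= 0 & p_all <= 1))
  p_single <- vapply(seq_len(5), function(i) {
    predict_network(m, X[i, , , drop = FALSE])
  }, numeric(1))
  expect_equal(p_single, p_all[1:5], tolerance = 1e-5)
  # identical inputs inside one batch give identical outputs
  Xdup <- one_hot_encode(c(seqs[1], seqs[1]))
  pd <- predict_network(m, Xdup)
  expect_identical(pd[1], pd[2])
})

test_that("prediction rejects inputs of the wrong length", {
  m <- build_corenup(tiny_model_config(24L), seed = 1)
  expect_error(predict_network(m, random_seqs(2, 30)),
               "expected 24, got 30")
})

test_that("models survive a save/load round trip", {
  m <- build_corenup(tiny_model_config(), seed = 4)
  path <- tempfile(fileext = ".rds")
  write_nucnet(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- read_nucnet(path)
  X <- one_hot_encode(random_seqs(4, 24))
  expect_identical(predict_network(m, X), predict_network(m2, X))
})
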