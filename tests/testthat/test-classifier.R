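# Vertex classifier: hidden size, training-set assembly, training,
# prediction, Youden threshold.

test_that("hidden size follows control-cohort PCA", {
  set.seed(1)
  # rank-1 structure plus tiny noise
  x1 <- outer(stats::rnorm(200), c(1, 2, 3, 4)) +
    matrix(stats::rnorm(800, sd = 1e-8), 200)
  expect_equal(select_hidden_size(x1), 1L)
  # isotropic 4-D Gaussian needs all four components
  x2 <- matrix(stats::rnorm(4000), 1000, 4)
  expect_equal(select_hidden_size(x2), 4L)
  # prescribed eigenvalue shares (0.6, 0.38, 0.015, 0.005):
  # cumulative 0.6, 0.98, 0.995 -> 3 components
  x0 <- scale(matrix(stats::rnorm(400), 100, 4), scale = FALSE)
  sv <- svd(x0)
  x3 <- sv$u %*% diag(sqrt(c(0.6, 0.38, 0.015, 0.005))) %*% t(sv$v)
  expect_equal(select_hidden_size(x3), 3L)
})

test_that("training set is balanced, contralateral, seeded, leak-free", {
  world <- acceptance_world()
  subj <- lapply(world$prepared$subjects[1:2], function(s)
    list(id = s$id, features = s$features,
         mask = list(hemisphere = s$mask$hemisphere,
                     vertices = s$mask$vertices[
                       seq_len(min(100, length(s$mask$vertices)))])))
  ts <- assemble_training_set(subj, seed = 9L)
  n_mask <- sum(vapply(subj, function(s) length(s$mask$vertices),
                       integer(1)))
  expect_equal(length(ts$y), 2L * n_mask)
  expect_equal(sum(ts$y == 1), n_mask)
  for (s in subj) {
    sel <- ts$subject == s$id
    expect_equal(sum(ts$y[sel] == 1), sum(ts$y[sel] == 0))
    # healthy rows strictly contralateral
    expect_true(all(ts$hemisphere[sel & ts$y == 0] !=
                      s$mask$hemisphere))
    # lesional rows are exactly the mask
    expect_setequal(ts$vertex[sel & ts$y == 1], s$mask$vertices)
  }
  ts2 <- assemble_training_set(subj, seed = 9L)
  expect_identical(ts, ts2)
  # sampling without replacement
  expect_false(any(duplicated(
    ts$vertex[ts$subject == subj[[1]]$id & ts$y == 0])))

  bil <- subj[[1]]
  bil$mask$hemisphere <- c("left", "right")
  expect_error(assemble_training_set(list(bil)), "unilateral")

  big <- subj[[1]]
  big$mask$vertices <- seq_len(world$prepared$pair$n_vertices + 1)
  expect_error(assemble_training_set(list(big)), "larger")
})

test_that("network separates separable clouds, is seeded, fails nulls", {
  set.seed(2)
  d <- 20; n <- 300
  x <- rbind(matrix(stats::rnorm(n * d), n),
             matrix(stats::rnorm(n * d, mean = 6 / sqrt(d)), n))
  colnames(x) <- paste0("f", 1:d)
  y <- rep(0:1, each = n)
  m <- suppressWarnings(train_network(x, y, hidden_size = 4, seed = 3L))
  acc <- mean((predict_vertices(m, x) >= 0.5) == y)
  expect_gte(acc, 0.99)
  m2 <- suppressWarnings(train_network(x, y, hidden_size = 4, seed = 3L))
  expect_identical(m$w1, m2$w1)
  expect_identical(m$w2, m2$w2)

  # shuffled labels: held-out accuracy is chance
  set.seed(4)
  ys <- sample(y)
  tr <- sample(length(ys), length(ys) / 2)
  mn <- suppressWarnings(train_network(x[tr, ], ys[tr], hidden_size = 4,
                                       seed = 5L))
  acc_held <- mean((predict_vertices(mn, x[-tr, ]) >= 0.5) == ys[-tr])
  expect_lt(abs(acc_held - 0.5), 0.06)

  expect_error(train_network(x, rep(1, nrow(x)), hidden_size = 2),
               "both classes")
  expect_error(predict_vertices(m, x[, 1:7]), "model expects")
  # batch equals row-by-row
  sc_batch <- predict_vertices(m, x[1:5, ])
  sc_rows <- vapply(1:5, function(i)
    predict_vertices(m, x[i, , drop = FALSE]), numeric(1))
  expect_equal(sc_batch, sc_rows)
})

test_that("model serialization round-trips predictions exactly", {
  set.seed(6)
  x <- matrix(stats::rnorm(200), 20)
  colnames(x) <- paste0("f", 1:10)
  m <- suppressWarnings(train_network(x, rep(0:1, 10), hidden_size = 2,
                                      seed = 1L, maxit = 50))
  p <- withr::local_tempfile(fileext = ".json")
  write_model(m, p)
  m2 <- read_model(p)
  expect_equal(predict_vertices(m2, x), predict_vertices(m, x))
})

test_that("Youden threshold matches exhaustive search with the tie rule", {
  # worked example: separable scores on a 0.05 grid -> highest tying
  # threshold 0.80 with J = 100
  t0 <- youden_threshold(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0),
                         grid = seq(0.05, 0.95, by = 0.05))
  expect_equal(as.numeric(t0), 0.80)
  expect_equal(attr(t0, "youden"), 100)
  # perfectly interleaved scores are uninformative
  ti <- youden_threshold(c(0.1, 0.3, 0.5, 0.7), c(1, 0, 1, 0),
                         grid = seq(0.05, 0.95, by = 0.05))
  expect_equal(attr(ti, "youden"), 0)
  expect_error(youden_threshold(runif(5), rep(1, 5)), "both classes")

  # oracle equivalence on random instances
  grid <- seq(0.01, 0.99, by = 0.01)
  set.seed(8)
  for (rep in 1:20) {
    sc <- stats::runif(60)
    y <- stats::rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    got <- youden_threshold(sc, y, grid)
    j <- sapply(grid, function(t)
      100 * (mean(sc[y == 1] >= t) + mean(sc[y == 0] < t) - 1))
    want <- max(grid[abs(j - max(j)) < 1e-12])
    expect_equal(as.numeric(got), want)
    expect_equal(attr(got, "youden"), max(j))
  }
})
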