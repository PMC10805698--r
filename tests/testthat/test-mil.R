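# The backward pass is hand-derived; these tests pin it against finite
# differences and check the aggregation contracts the model relies on.

gradcheck_case <- function(cfg_args, sf_dim = 0, nonneg = FALSE) {
  set.seed(99)
  n <- 12L; nb <- 4L; d <- 5L
  x <- matrix(stats::rnorm(n * d), n, d)
  if (nonneg) x <- abs(x)
  bag <- rep(1:nb, each = 3L)
  y <- sample(1:2, nb, replace = TRUE)
  sf <- if (sf_dim > 0) matrix(stats::rnorm(nb * sf_dim), nb, sf_dim)
  cfg <- do.call(mil_config,
                 c(list(n_classes = 2, seed = 7,
                        sample_feature_dim = sf_dim), cfg_args))
  m <- mil_new(d, cfg)
  w <- stats::runif(nb, 0.5, 2)
  lg <- mutmil:::mil_loss_grad(m, x, bag, nb, y, weights = w, sf = sf,
                               training = FALSE)
  ng <- mutmil:::mil_numeric_grad(m, x, bag, nb, y, weights = w, sf = sf)
  worst <- 0
  for (nm in names(ng)) {
    rel <- max(abs(lg$grads[[nm]] - ng[[nm]])) / (max(abs(ng[[nm]])) + 1e-8)
    worst <- max(worst, rel)
  }
  worst
}

test_that("analytic gradients match finite differences in every mode", {
  cases <- list(
    list(aggregation = "mean", encoder_widths = 6, head_widths = 4,
         attention_l1 = 0.05, l2 = 0.01),
    list(aggregation = "sum", n_heads = 3, encoder_widths = c(6, 4),
         encoder_activation = "relu"),
    list(aggregation = "dynamic", encoder_widths = 6, attention_l1 = 0.03),
    list(aggregation = "dynamic", dynamic_second = "sum", encoder_widths = 6)
  )
  for (cs in cases) expect_lt(gradcheck_case(cs), 1e-4)
  expect_lt(gradcheck_case(list(aggregation = "sum",
                                attention_frozen = TRUE, output = "asu"),
                           nonneg = TRUE), 1e-4)
  expect_lt(gradcheck_case(list(aggregation = "mean", encoder_widths = 6,
                                output = "asu", head_widths = 3),
                           sf_dim = 2), 1e-4)
})

test_that("convolutional kernel gradients match finite differences", {
  set.seed(99)
  n <- 10L; nb <- 3L; d <- 24L
  x <- matrix(stats::rbinom(n * d, 1, 0.3), n, d)
  bag <- rep(1:nb, c(4L, 3L, 3L)); y <- c(1L, 2L, 1L)
  cfg <- mil_config(n_classes = 2, aggregation = "sum",
                    kernel_slices = list(1:12, 13:24), kernel_units = 3,
                    kernel_type = "conv", kernel_width = 2,
                    encoder_widths = 5, seed = 7)
  m <- mil_new(d, cfg)
  lg <- mutmil:::mil_loss_grad(m, x, bag, nb, y, training = FALSE)
  ng <- mutmil:::mil_numeric_grad(m, x, bag, nb, y)
  for (nm in names(ng)) {
    rel <- max(abs(lg$grads[[nm]] - ng[[nm]])) / (max(abs(ng[[nm]])) + 1e-8)
    expect_lt(rel, 1e-4)
  }
})

test_that("predictions are invariant to instance order in every mode", {
  for (agg in c("mean", "sum", "dynamic")) {
    bags <- random_bags(20, seed = 11)
    cfg <- mil_config(n_classes = 2, n_heads = 2, aggregation = agg,
                      encoder_widths = 8, seed = 5)
    m <- mil_new(ncol(bags$x), cfg)
    p1 <- predict(m, bags)
    set.seed(42)
    p2 <- predict(m, shuffle_instances(bags))
    expect_equal(p1, p2, tolerance = 1e-6)
  }
})

test_that("a bag of identical instances reduces to the single instance", {
  cfg <- mil_config(n_classes = 2, n_heads = 2, aggregation = "mean",
                    encoder_widths = 8, seed = 5)
  m <- mil_new(4, cfg)
  one <- matrix(abs(stats::rnorm(4)), 1)
  many <- one[rep(1, 7), , drop = FALSE]
  b1 <- mil_bags(one, 1L, n_bags = 1L)
  b7 <- mil_bags(many, rep(1L, 7), n_bags = 1L)
  expect_equal(predict(m, b1), predict(m, b7), tolerance = 1e-10)
})

test_that("sum aggregation is the log1p of the attention-weighted sum", {
  cfg <- mil_config(n_classes = 2, n_heads = 1, aggregation = "sum",
                    attention_frozen = TRUE, seed = 1)
  m <- mil_new(2, cfg)
  x <- rbind(c(1, 0), c(3, 0))
  cache <- mutmil:::mil_forward(m, x, c(1L, 1L), 1L)
  expect_equal(as.numeric(cache$S), c(log(5), 0))
})

test_that("duplicating an attended instance never shrinks the sum", {
  cfg <- mil_config(n_classes = 2, n_heads = 2, aggregation = "sum",
                    encoder_widths = 6, seed = 3)
  m <- mil_new(4, cfg)
  x <- matrix(abs(stats::rnorm(20)), 5, 4)
  bag <- rep(1L, 5)
  before <- mutmil:::mil_forward(m, x, bag, 1L)
  after <- mutmil:::mil_forward(m, rbind(x, x[2, ]), rep(1L, 6), 1L)
  for (k in 1:2) {
    expect_true(all(after$P[[k]] >= before$P[[k]] - 1e-12))
  }
})

test_that("probabilities are proper and a zeroed output layer is uniform", {
  bags <- random_bags(10, seed = 2)
  for (out in c("softmax", "asu")) {
    cfg <- mil_config(n_classes = 2, aggregation = "mean",
                      encoder_widths = 6, output = out, seed = 4)
    m <- mil_new(ncol(bags$x), cfg)
    pr <- predict(m, bags)
    expect_equal(unname(rowSums(pr)), rep(1, 10), tolerance = 1e-6)
    m$params$out_W[] <- 0
    m$params$out_b[] <- 0
    pr0 <- predict(m, bags)
    expect_equal(unname(pr0), matrix(0.5, 10, 2), tolerance = 1e-9)
  }
})

test_that("attention weights are strictly inside (0,1) and feature-determined", {
  bags <- random_bags(10, seed = 6)
  cfg <- mil_config(n_classes = 2, n_heads = 3, aggregation = "mean",
                    encoder_widths = 6, seed = 8)
  m <- mil_new(ncol(bags$x), cfg)
  a <- attention_weights(m, bags)
  expect_true(all(a > 0 & a < 1))
  expect_equal(ncol(a), 3L)
  x <- matrix(abs(stats::rnorm(ncol(bags$x))), 1)
  dup <- mil_bags(x[rep(1, 4), ], rep(1L, 4), n_bags = 1L)
  ad <- attention_weights(m, dup)
  expect_equal(ad, ad[rep(1, 4), , drop = FALSE])
})

test_that("evaluation refuses empty bags", {
  bags <- random_bags(3, seed = 9)
  bags$n_bags <- 4L
  bags$sample_ids <- c(bags$sample_ids, "empty")
  bags$labels <- NULL
  cfg <- mil_config(n_classes = 2, seed = 1)
  m <- mil_new(ncol(bags$x), cfg)
  expect_error(predict(m, bags), "empty bag")
})

test_that("the reference binary architecture builds and predicts", {
  sl <- sequence_component_slices(6)
  cfg <- msi_reference_config(sl, seed = 2)
  expect_equal(cfg$attention_l1, 0.05)
  expect_equal(cfg$l2, 0.01)
  expect_equal(cfg$instance_dropout, 0.4)
  expect_equal(cfg$n_heads, 1L)
  m <- mil_new(8 * 24, cfg)
  x <- matrix(stats::rbinom(5 * 192, 1, 0.25), 5, 192)
  pr <- predict(m, mil_bags(x, rep(1L, 5), n_bags = 1L))
  expect_equal(unname(rowSums(pr)), 1, tolerance = 1e-9)
})
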