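mk_grid <- function(v, bin = 1L, class = "del_like",
                    origin = c(x = 0, y = 0)) {
  structure(list(values = v, origin = origin, bin = bin, class = class),
            class = "cluster_grid")
}

interior_grid <- function(n, pad) {
  v <- matrix(0, n, n)
  k <- n - 2 * pad + 1
  v[pad:(n - pad), pad:(n - pad)] <- matrix(runif(k * k), k)
  v
}

test_that("forward/conjugate operators are adjoint and A*A is PSD", {
  set.seed(401)
  model <- insert_model(20, 3)
  n <- 101
  pad <- 40
  for (cls in c("del_like", "dup_like", "inv_pp", "inv_mm")) {
    for (r in 1:4) {
      u <- interior_grid(n, pad)
      v <- interior_grid(n, pad)
      Au <- apply_forward(mk_grid(u, class = cls), model)$values
      Asv <- apply_conjugate(mk_grid(v, class = cls), model)$values
      expect_lt(abs(sum(Au * v) - sum(u * Asv)) / abs(sum(Au * v)), 1e-8)
    }
  }
  # u . A*A u = ||A u||^2 >= 0
  u <- interior_grid(n, pad)
  Au <- apply_forward(mk_grid(u), model)$values
  AAu <- apply_conjugate(mk_grid(Au), model)$values
  expect_gte(sum(u * AAu), 0)
  expect_lt(abs(sum(u * AAu) - sum(Au * Au)) / sum(Au * Au), 1e-8)
})

test_that("A*A equals the symmetric composite diffusion", {
  set.seed(402)
  model <- insert_model(20, 3)
  n <- 121
  pm <- matrix(0, n, n)
  pm[61, 61] <- 1
  for (input in list(pm, interior_grid(n, 45))) {
    a <- apply_conjugate(
      mk_grid(apply_forward(mk_grid(input), model)$values), model)$values
    b <- normal_operator(mk_grid(input), model)$values
    # discrete Gaussian factors compose only approximately; the residual
    # shrinks with the kernel scale (here sigma ~ 2 bins)
    expect_lt(max(abs(a - b)) / max(a), 1e-4)
    # the composite is symmetric: no net displacement of a point mass
    if (identical(input, pm)) {
      am <- which(b == max(b), arr.ind = TRUE)[1, ]
      expect_equal(unname(am), c(61, 61))
      expect_equal(b, t(b), tolerance = 1e-12)
    }
  }
})

test_that("operator factors commute and conserve mass", {
  model <- insert_model(30, 4)
  n <- 161
  pm <- matrix(0, n, n)
  pm[81, 81] <- 1
  p <- svbwt:::op_params(mk_grid(pm), model)
  o1 <- svbwt:::grid_gauss_cpp(
    svbwt:::grid_diag_box_cpp(
      svbwt:::grid_translate_cpp(pm, -p$h, p$h), p$h, FALSE), p$sigma_axis)
  o2 <- svbwt:::grid_translate_cpp(
    svbwt:::grid_diag_box_cpp(
      svbwt:::grid_gauss_cpp(pm, p$sigma_axis), p$h, FALSE), -p$h, p$h)
  expect_lt(max(abs(o1 - o2)), 1e-8)
  expect_equal(sum(o1), 1, tolerance = 1e-3)
  # zero grid stays zero
  z <- apply_forward(mk_grid(matrix(0, 61, 61)), insert_model(10, 1))
  expect_true(all(z$values == 0))
  # insufficient padding raises an error
  edge <- matrix(0, 61, 61)
  edge[2, 2] <- 1
  expect_error(apply_forward(mk_grid(edge), insert_model(40, 5)),
               "padding")
})

test_that("a single pair's conjugate peaks at the class displacement", {
  model <- insert_model(20, 3)
  n <- 101
  for (cls in c("del_like", "dup_like", "inv_pp", "inv_mm")) {
    v <- matrix(0, n, n)
    v[51, 51] <- 1
    z <- apply_conjugate(mk_grid(v, class = cls), model)$values
    am <- which(z == max(z), arr.ind = TRUE)[1, ]
    d <- svbwt:::class_geometry(cls)$d
    expect_lte(abs(am[1] - (51 - d[1] * 10)), 1)
    expect_lte(abs(am[2] - (51 - d[2] * 10)), 1)
  }
})

test_that("apply_forward matches the two-step generative sampling rule", {
  set.seed(403)
  model <- insert_model(760, 45)
  n <- 2401
  c0 <- 1201
  pm <- matrix(0, n, n)
  pm[c0, c0] <- 1
  fw <- apply_forward(mk_grid(pm), model)$values
  N <- 1e5
  l <- rnorm(N, 760, 45)
  u <- runif(N) * l
  dx <- -u
  dy <- l - u
  coords <- seq_len(n) - c0
  ix <- rowSums(fw)
  iy <- colSums(fw)
  mx <- sum(coords * ix)
  sx <- sqrt(sum((coords - mx)^2 * ix))
  my <- sum(coords * iy)
  sy <- sqrt(sum((coords - my)^2 * iy))
  # marginal means within Monte-Carlo error, sds within 2%
  expect_lt(abs(mx - mean(dx)), 4 * sd(dx) / sqrt(N) + 1)
  expect_lt(abs(my - mean(dy)), 4 * sd(dy) / sqrt(N) + 1)
  expect_lt(abs(sx - sd(dx)) / sd(dx), 0.02)
  expect_lt(abs(sy - sd(dy)) / sd(dy), 0.02)
  # the insert-length marginal (y - x) is Gaussian N(L, sigma): compare
  # mean and sd through sampled cells of the operator output
  qs <- dy - dx
  expect_lt(abs(mean(qs) - 760), 1)
  expect_lt(abs(sd(qs) - 45) / 45, 0.02)
})

test_that("thresholding recovers regions, including composite clusters", {
  set.seed(404)
  model <- insert_model(760, 45)
  # a single pair yields one region containing the displaced argmax
  pts <- data.table::data.table(x = 5000, y = 9000)
  g <- cluster_grid(pts, model, "del_like", bin = 4)
  r <- predict_regions(apply_conjugate(g, model))
  expect_equal(nrow(r), 1)
  expect_true(r$a_lo <= 5380 & r$a_hi >= 5380)
  expect_true(r$b_lo <= 8620 & r$b_hi >= 8620)

  # region recovery: p pairs from one junction -> one region containing it
  hits <- 0
  reps <- 40
  for (i in seq_len(reps)) {
    pts <- sample_pairs_for_junction(12, 50000, 90000, "del_like")
    g <- cluster_grid(pts, model, "del_like", bin = 4)
    r <- predict_regions(apply_conjugate(g, model))
    if (nrow(r) >= 1 && any(r$a_lo <= 50000 & r$a_hi >= 50000 &
                              r$b_lo <= 90000 & r$b_hi >= 90000))
      hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)

  # two junctions >= 3L apart in one composite cluster -> two regions
  two <- rbind(sample_pairs_for_junction(15, 50000, 90000, "del_like"),
               sample_pairs_for_junction(15, 52500, 92500, "del_like"))
  g <- cluster_grid(two, model, "del_like", bin = 4)
  r <- predict_regions(apply_conjugate(g, model))
  expect_gte(nrow(r), 2)
  expect_true(any(r$a_lo <= 50000 & r$a_hi >= 50000))
  expect_true(any(r$a_lo <= 52500 & r$a_hi >= 52500))

  # all-zero grid: no regions
  g0 <- mk_grid(matrix(0, 50, 50))
  expect_equal(nrow(predict_regions(g0)), 0)
})

test_that("the insert model is estimated robustly", {
  set.seed(405)
  tl <- round(rnorm(5000, 760, 45))
  pairs <- data.table::data.table(proper = TRUE, tlen = tl)
  m <- estimate_insert_model(pairs)
  expect_lt(abs(m$mean - 760) / 760, 0.01)
  expect_lt(abs(m$sd - 45) / 45, 0.05)
  # 5% contamination at 10 L barely moves the estimate
  cont <- data.table::data.table(
    proper = TRUE, tlen = c(tl, rep(7600L, 250)))
  mc <- estimate_insert_model(cont)
  expect_lt(abs(mc$mean - 760) / 760, 0.02)
  expect_lt(abs(mc$sd - 45) / 45, 0.1)
  # constant template length: sd floored at 1
  const <- data.table::data.table(proper = TRUE, tlen = rep(500L, 2000))
  expect_equal(estimate_insert_model(const)$sd, 1)
  # too few pairs: explicit error asking for configuration
  expect_error(estimate_insert_model(pairs[1:10]), "too few")
})
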