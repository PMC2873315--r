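# sparse multivariate polynomial layer

test_that("parsing, arithmetic and evaluation agree on random points", {
  vars <- c("x", "y", "z")
  p <- discrimODE:::poly_parse("2*x^2*y - 3*z + 0.5*(x - y)^2 + 1", vars)
  q <- discrimODE:::poly_parse("x*z - y^3 + 4", vars)
  ref_p <- function(x, y, z) 2 * x^2 * y - 3 * z + 0.5 * (x - y)^2 + 1
  ref_q <- function(x, y, z) x * z - y^3 + 4
  set.seed(11)
  for (i in 1:20) {
    pt <- stats::setNames(rnorm(3), vars)
    expect_equal(discrimODE:::poly_eval(p, pt), do.call(ref_p, as.list(pt)))
    pq <- discrimODE:::poly_mul(p, q)
    expect_equal(discrimODE:::poly_eval(pq, pt),
                 do.call(ref_p, as.list(pt)) * do.call(ref_q, as.list(pt)),
                 tolerance = 1e-12)
  }
})

test_that("differentiation and affine substitution are consistent", {
  vars <- c("u", "v")
  p <- discrimODE:::poly_parse("u^3*v - 2*u*v^2 + v", vars)
  dp <- discrimODE:::poly_diff(p, "u")
  set.seed(5)
  for (i in 1:10) {
    pt <- stats::setNames(rnorm(2), vars)
    expect_equal(discrimODE:::poly_eval(dp, pt),
                 3 * pt[["u"]]^2 * pt[["v"]] - 2 * pt[["v"]]^2)
  }
  # substitute u -> 2u + 1, v -> v - 3 and check by evaluation
  ps <- discrimODE:::poly_subst_affine(p, shift = c(u = 1, v = -3),
                                       scale = c(u = 2, v = 1))
  pt <- c(u = 0.7, v = -0.2)
  expect_equal(discrimODE:::poly_eval(ps, pt),
               discrimODE:::poly_eval(p, c(u = 2 * 0.7 + 1, v = -0.2 - 3)))
})

test_that("parser flags undeclared symbols and rational terms", {
  expect_error(discrimODE:::poly_parse("x + Z", "x"),
               class = "discrim_symbol_error")
  expect_error(discrimODE:::poly_parse("1/(1 + x)", "x"),
               class = "discrim_rational_error")
  # division by a constant is polynomial
  p <- discrimODE:::poly_parse("x/2", "x")
  expect_equal(p$coef, 0.5)
})

test_that("exact multivariate division recovers factors", {
  vars <- c("a", "b")
  A <- discrimODE:::poly_parse("(a + 2*b)*(a^2 - b + 1)", vars)
  B <- discrimODE:::poly_parse("a + 2*b", vars)
  Q <- discrimODE:::poly_div_exact(A, B)
  expect_false(is.null(Q))
  expect_lt(discrimODE:::poly_coef_dist(
    discrimODE:::poly_mul(Q, B), A), 1e-12)
  # non-exact division fails
  C <- discrimODE:::poly_parse("a + b", vars)
  expect_null(discrimODE:::poly_div_exact(A, C))
})

test_that("monomial enumeration has the right counts", {
  expect_equal(nrow(discrimODE:::monomials_upto(3, 2)), choose(5, 2))
  expect_equal(nrow(discrimODE:::monomials_upto(2, 3, dmin = 1)),
               choose(5, 3) - 1)
})
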