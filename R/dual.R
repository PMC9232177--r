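#' Dual numbers: minimal forward-mode automatic differentiation
#'
#' A dual carrier holds a value vector \code{a} and a partials matrix
#' \code{b} (one column per seeded direction), and propagates
#' \code{f(a + sum_i b_i eps_i) = f(a) + sum_i eps_i df(a) b_i} through the
#' elementary operations \code{+ - * / ^ exp log sin cos sqrt}.  Seeding
#' several unit directions at once ("chunking") extracts several Jacobian
#' columns per pass.  Only first-order partials are carried.
#'
#' @param value numeric vector of primal values.
#' @param deriv numeric matrix of partials, \code{length(value)} rows and
#'   one column per direction; a vector is taken as a single column.
#' @return an object of class \code{"dual"}.
#' @export
dual <- function(value, deriv) {
  if (is.vector(deriv)) deriv <- matrix(deriv, nrow = length(value))
  stopifnot(is.numeric(value), nrow(deriv) == length(value))
  structure(list(v = as.numeric(value), d = deriv), class = "dual")
}

#' @rdname dual
#' @param x a dual number (or plain numeric, returned unchanged/zero).
#' @export
dual_value <- function(x) if (inherits(x, "dual")) x$v else x

#' @rdname dual
#' @export
dual_deriv <- function(x) {
  if (inherits(x, "dual")) x$d else matrix(0, length(x), 0)
}

#' @export
print.dual <- function(x, ...) {
  cat(sprintf("<dual> %d value(s), %d direction(s)\n",
              length(x$v), ncol(x$d)))
  invisible(x)
}

as_dual <- function(x, ndir) {
  if (inherits(x, "dual")) x else dual(x, matrix(0, length(x), ndir))
}

# recycle scalars against vectors, as base arithmetic does
recycle2 <- function(a, b) {
  n <- max(length(a$v), length(b$v))
  expand <- function(z) {
    if (length(z$v) == n) return(z)
    if (length(z$v) != 1) stop("dual: incompatible lengths")
    dual(rep(z$v, n), matrix(rep(z$d, each = n), nrow = n))
  }
  list(expand(a), expand(b))
}

#' @export
Ops.dual <- function(e1, e2) {
  if (.Generic %in% c("==", "!=", "<", ">", "<=", ">="))
    stop(sprintf("dual numbers do not support comparison '%s' (branching on parameter values is not differentiable)", .Generic))
  if (missing(e2)) {             # unary + / -
    if (.Generic == "-") return(dual(-e1$v, -e1$d))
    if (.Generic == "+") return(e1)
    stop(sprintf("dual: unsupported unary operation '%s'", .Generic))
  }
  ndir <- max(ncol(dual_deriv(e1)), ncol(dual_deriv(e2)))
  ab <- recycle2(as_dual(e1, ndir), as_dual(e2, ndir))
  a <- ab[[1]]; b <- ab[[2]]
  switch(.Generic,
    "+" = dual(a$v + b$v, a$d + b$d),
    "-" = dual(a$v - b$v, a$d - b$d),
    "*" = dual(a$v * b$v, a$d * b$v + b$d * a$v),
    "/" = dual(a$v / b$v, (a$d * b$v - b$d * a$v) / b$v^2),
    "^" = {
      val <- a$v^b$v
      # d(a^b) = a^b * (db*log a + b*da/a); log a term drops for constant b
      term_a <- a$d * (b$v * a$v^(b$v - 1))
      term_b <- if (all(b$d == 0)) 0 else b$d * (val * log(a$v))
      dual(val, term_a + term_b)
    },
    stop(sprintf("dual: unsupported operation '%s'", .Generic)))
}

#' @export
Math.dual <- function(x, ...) {
  switch(.Generic,
    exp  = dual(exp(x$v),  x$d * exp(x$v)),
    log  = dual(log(x$v),  x$d / x$v),
    sin  = dual(sin(x$v),  x$d * cos(x$v)),
    cos  = dual(cos(x$v), -x$d * sin(x$v)),
    sqrt = dual(sqrt(x$v), x$d / (2 * sqrt(x$v))),
    stop(sprintf("dual: unsupported primitive '%s'", .Generic)))
}

#' @export
`[.dual` <- function(x, i) dual(x$v[i], x$d[i, , drop = FALSE])

#' @export
length.dual <- function(x) length(x$v)

#' @export
c.dual <- function(...) {
  parts <- list(...)
  ndir <- max(vapply(parts, function(z) ncol(dual_deriv(z)), integer(1)))
  parts <- lapply(parts, as_dual, ndir = ndir)
  dual(unlist(lapply(parts, `[[`, "v")),
       do.call(rbind, lapply(parts, `[[`, "d")))
}

#' @export
sum.dual <- function(..., na.rm = FALSE) {
  z <- c.dual(...)
  dual(sum(z$v), matrix(colSums(z$d), nrow = 1))
}

#' Dual-number (forward-mode) Jacobian
#'
#' Assembles the Jacobian of \code{f} at \code{p} by seeding up to
#' \code{chunk} unit dual directions per pass.  The result is identical, to
#' roundoff, for any chunk size; chunking only trades passes against carrier
#' width.  \code{f} must be written with the supported primitives
#' (arithmetic, powers, \code{exp}, \code{log}, \code{sin}, \code{cos},
#' \code{sqrt}); any other operation raises an error naming it.
#'
#' @inheritParams cs_jacobian
#' @param chunk number of directions seeded per pass, between 1 and
#'   \code{length(p)}.
#' @return a \code{derivative_result} with \code{engine = "dual"},
#'   \code{step = 0}.
#' @export
dual_jacobian <- function(f, p, chunk = length(p)) {
  stopifnot(chunk >= 1, chunk <= length(p))
  f <- as_target_fn(f, p)
  n <- length(p)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  cols <- vector("list", length(blocks))
  value <- NULL
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    seed <- matrix(0, n, length(idx))
    seed[cbind(idx, seq_along(idx))] <- 1
    out <- f(dual(p, seed))
    value <- dual_value(out)
    cols[[b]] <- dual_deriv(out)
  }
  J <- do.call(cbind, cols)
  check_finite_cols(J, "dual_jacobian")
  new_derivative_result(value, J, "dual", 0)
}
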