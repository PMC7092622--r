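#' Exact rational numbers
#'
#' Stoichiometric coefficients and solved fluxes are kept as exact rationals
#' so that quantities such as a net ATP yield of 3/4 come out exact rather
#' than as floating-point approximations.  A rational vector stores integer
#' numerators and positive integer denominators (as doubles, which represent
#' integers exactly up to 2^53; magnitudes are guarded well below that).
#'
#' @param n numerator(s), integer-valued.
#' @param d denominator(s), integer-valued and non-zero; recycled against `n`.
#' @return an object of class `"rational"`.
#' @examples
#' rational(3, 4) + rational(1, 4)  # 1
#' as.numeric(rational(1, 3) * 3)   # exactly 1
#' @export
rational <- function(n, d = 1) {
  if (any(!is.finite(n)) || any(!is.finite(d)))
    stop("rational parts must be finite")
  if (any(n != round(n)) || any(d != round(d)))
    stop("rational parts must be integer-valued")
  if (any(d == 0)) stop("zero denominator")
  k <- if (length(n) == 0 || length(d) == 0) 0 else max(length(n), length(d))
  n <- rep_len(as.double(n), k)
  d <- rep_len(as.double(d), k)
  .rat_reduce(n, d)
}

.rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    t <- b
    b <- ifelse(b > 0, a %% b, 0)
    a <- t
  }
  ifelse(a == 0, 1, a)
}

.rat_guard <- function(x) {
  if (any(abs(x) > 2^50))
    stop("rational overflow: intermediate value exceeds exact integer range")
  x
}

.rat_reduce <- function(n, d) {
  s <- ifelse(d < 0, -1, 1)
  n <- n * s; d <- d * s
  g <- .rat_gcd(n, d)
  structure(list(n = .rat_guard(n / g), d = .rat_guard(d / g)),
            class = "rational")
}

#' @export
is_rational <- function(x) inherits(x, "rational")

.as_rat <- function(x) {
  if (is_rational(x)) return(x)
  rational(x, 1)
}

#' @export
length.rational <- function(x) length(x$n)

#' @export
`[.rational` <- function(x, i) .rat_reduce(x$n[i], x$d[i])

#' @export
`[<-.rational` <- function(x, i, value) {
  value <- .as_rat(value)
  x$n[i] <- value$n
  x$d[i] <- value$d
  .rat_reduce(x$n, x$d)
}

#' @export
c.rational <- function(...) {
  parts <- lapply(list(...), .as_rat)
  .rat_reduce(unlist(lapply(parts, `[[`, "n")),
              unlist(lapply(parts, `[[`, "d")))
}

#' @export
as.double.rational <- function(x, ...) x$n / x$d

#' @export
as.character.rational <- function(x, ...) {
  ifelse(x$d == 1, format(x$n, scientific = FALSE, trim = TRUE),
         paste0(format(x$n, scientific = FALSE, trim = TRUE), "/",
                format(x$d, scientific = FALSE, trim = TRUE)))
}

#' @export
format.rational <- function(x, ...) as.character(x)

#' @export
print.rational <- function(x, ...) {
  cat("<rational>", as.character(x), "\n")
  invisible(x)
}

#' @export
rep.rational <- function(x, ...) {
  i <- rep(seq_along(x$n), ...)
  .rat_reduce(x$n[i], x$d[i])
}

#' @export
sum.rational <- function(..., na.rm = FALSE) {
  x <- c.rational(...)
  acc_n <- 0; acc_d <- 1
  for (i in seq_along(x$n)) {
    acc_n <- .rat_guard(acc_n * x$d[i] + x$n[i] * acc_d)
    acc_d <- .rat_guard(acc_d * x$d[i])
    g <- .rat_gcd(acc_n, acc_d)
    acc_n <- acc_n / g; acc_d <- acc_d / g
  }
  .rat_reduce(acc_n, acc_d)
}

#' @export
abs.rational <- function(x) .rat_reduce(abs(x$n), x$d)

#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(.rat_reduce(-e1$n, e1$d))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rationals")
  }
  a <- .as_rat(e1); b <- .as_rat(e2)
  switch(.Generic,
    "+" = .rat_reduce(.rat_guard(a$n * b$d + b$n * a$d), .rat_guard(a$d * b$d)),
    "-" = .rat_reduce(.rat_guard(a$n * b$d - b$n * a$d), .rat_guard(a$d * b$d)),
    "*" = .rat_reduce(.rat_guard(a$n * b$n), .rat_guard(a$d * b$d)),
    "/" = {
      if (any(b$n == 0)) stop("division by zero rational")
      .rat_reduce(.rat_guard(a$n * b$d), .rat_guard(a$d * b$n))
    },
    "==" = a$n * b$d == b$n * a$d,
    "!=" = a$n * b$d != b$n * a$d,
    "<"  = a$n * b$d <  b$n * a$d,
    "<=" = a$n * b$d <= b$n * a$d,
    ">"  = a$n * b$d >  b$n * a$d,
    ">=" = a$n * b$d >= b$n * a$d,
    stop(.Generic, " not defined for rationals")
  )
}

#' Parse rationals written as "p/q" strings
#'
#' Accepts integers, "p/q" strings and numerics that are exactly
#' representable as small fractions (denominator up to 10^6).
#' @param x character, numeric or rational.
#' @return a rational vector.
#' @export
as_rational <- function(x) {
  if (is_rational(x)) return(x)
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)
    to_num <- function(s) suppressWarnings(as.double(s))
    n <- vapply(parts, function(p) to_num(p[1]), 0)
    d <- vapply(parts, function(p) if (length(p) > 1) to_num(p[2]) else 1, 0)
    if (any(is.na(n)) || any(is.na(d)))
      stop("cannot parse rational from: ", paste(x[is.na(n) | is.na(d)], collapse = ", "))
    return(rational(n, d))
  }
  if (is.numeric(x)) {
    n <- d <- numeric(length(x))
    for (i in seq_along(x)) {
      hit <- FALSE
      for (q in c(1, 2, 3, 4, 5, 6, 8, 10, 12, 16, 20, 24, 100, 1000, 10^6)) {
        if (abs(x[i] * q - round(x[i] * q)) < 1e-9) {
          n[i] <- round(x[i] * q); d[i] <- q; hit <- TRUE; break
        }
      }
      if (!hit) stop("numeric value ", x[i], " is not a small exact fraction")
    }
    return(rational(n, d))
  }
  stop("cannot coerce class ", paste(class(x), collapse = "/"), " to rational")
}

# --- exact linear algebra -------------------------------------------------

#' Solve a rational linear system by exact Gaussian elimination
#'
#' Row-reduces the augmented system `A x = b` over the rationals with a
#' deterministic pivot order (first non-zero entry scanning columns left to
#' right, rows top to bottom; no magnitude-based pivoting, no tolerances).
#'
#' @param A list with integer-valued numerator and denominator matrices
#'   (`n`, `d`) or a plain numeric matrix of integer-valued entries.
#' @param b right-hand side, rational or integer-valued numeric vector.
#' @return a list with elements `status` (one of `"unique"`,
#'   `"underdetermined"`, `"inconsistent"`), `x` (rational solution when
#'   unique), `pivots` (pivot column indices), `free` (free column indices)
#'   and `bad_rows` (indices of original rows participating in an
#'   inconsistency, when `status == "inconsistent"`).
#' @export
rational_solve <- function(A, b) {
  if (is.matrix(A)) A <- list(n = A, d = array(1, dim(A)))
  An <- A$n; Ad <- A$d
  m <- nrow(An); k <- ncol(An)
  b <- .as_rat(b)
  stopifnot(length(b) == m)
  # augmented numerator/denominator matrices, plus provenance of each row
  N <- cbind(An, b$n); D <- cbind(Ad, b$d)
  rowsrc <- lapply(seq_len(m), identity)  # original rows combined into row i

  r_is_zero <- function(i, j) N[i, j] == 0
  r_val <- function(i, j) rational(N[i, j], D[i, j])

  piv_rows <- integer(0); piv_cols <- integer(0)
  row <- 1
  for (col in seq_len(k)) {
    if (row > m) break
    pr <- 0
    for (i in row:m) if (!r_is_zero(i, col)) { pr <- i; break }
    if (pr == 0) next
    if (pr != row) {
      N[c(row, pr), ] <- N[c(pr, row), ]
      D[c(row, pr), ] <- D[c(pr, row), ]
      rowsrc[c(row, pr)] <- rowsrc[c(pr, row)]
    }
    # normalise pivot row
    p <- r_val(row, col)
    for (j in seq_len(k + 1)) {
      v <- r_val(row, j) / p
      N[row, j] <- v$n; D[row, j] <- v$d
    }
    # eliminate the column from all other rows
    for (i in seq_len(m)) {
      if (i == row || r_is_zero(i, col)) next
      f <- r_val(i, col)
      for (j in seq_len(k + 1)) {
        v <- r_val(i, j) - f * r_val(row, j)
        N[i, j] <- v$n; D[i, j] <- v$d
      }
      rowsrc[[i]] <- sort(unique(c(rowsrc[[i]], rowsrc[[row]])))
    }
    piv_rows <- c(piv_rows, row); piv_cols <- c(piv_cols, col)
    row <- row + 1
  }

  # inconsistent rows: all-zero coefficients, non-zero rhs
  bad <- integer(0)
  if (row <= m) {
    for (i in row:m) {
      if (all(N[i, seq_len(k)] == 0) && N[i, k + 1] != 0)
        bad <- sort(unique(c(bad, rowsrc[[i]])))
    }
  }
  if (length(bad) > 0)
    return(list(status = "inconsistent", x = NULL, pivots = piv_cols,
                free = setdiff(seq_len(k), piv_cols), bad_rows = bad))
  free <- setdiff(seq_len(k), piv_cols)
  if (length(free) > 0)
    return(list(status = "underdetermined", x = NULL, pivots = piv_cols,
                free = free, bad_rows = integer(0)))
  x <- rational(rep(0, k))
  for (t in seq_along(piv_cols)) x[piv_cols[t]] <- r_val(piv_rows[t], k + 1)
  list(status = "unique", x = x, pivots = piv_cols, free = integer(0),
       bad_rows = integer(0))
}
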