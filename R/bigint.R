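# Exact big-integer arithmetic for code-space counting.
#
# The counts involved (up to ~1e84) exceed double precision, so exact
# integers are represented as little-endian digit vectors in base 1e7
# stored in doubles (all intermediate products stay below 2^53).  Only
# the operations the closed forms need are provided: addition,
# subtraction, multiplication, exact division by a small integer,
# comparison and decimal formatting.

.BIGBASE <- 1e7

.big <- function(digits) {
  while (length(digits) > 1L && digits[length(digits)] == 0)
    digits <- digits[-length(digits)]
  structure(list(d = digits), class = "bigint")
}

#' Big integers for exact code-space counts
#'
#' A minimal arbitrary-precision integer type backing [spaceSize()] and
#' [totalSpaceSize()].  Construct from a non-negative double below 2^53 or
#' a decimal string; supports `+`, `-` (non-negative results only), `*`,
#' comparison, `as.character` and scientific formatting via [formatSci()].
#'
#' @param x A non-negative integer-valued number or a decimal string.
#' @return An object of class `"bigint"`.
#' @examples
#' bigint(20) * bigint("1000000000000000000")
#' @export
bigint <- function(x) {
  if (is.character(x)) {
    if (!grepl("^[0-9]+$", x)) stop("not a decimal integer string")
    n <- nchar(x)
    starts <- rev(seq(n, 1L, by = -7L))
    d <- vapply(starts, function(s)
      as.numeric(substr(x, max(1L, s - 6L), s)), numeric(1))
    return(.big(rev(d)))
  }
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  d <- numeric(0)
  repeat {
    d <- c(d, x %% .BIGBASE)
    x <- (x - x %% .BIGBASE) / .BIGBASE
    if (x == 0) break
  }
  .big(d)
}

.big_add <- function(a, b) {
  n <- max(length(a$d), length(b$d))
  x <- c(a$d, numeric(n - length(a$d)))
  y <- c(b$d, numeric(n - length(b$d)))
  s <- x + y
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- if (s[i] >= .BIGBASE) 1 else 0
    s[i] <- s[i] - carry * .BIGBASE
  }
  if (carry) s <- c(s, carry)
  .big(s)
}

.big_cmp <- function(a, b) {
  if (length(a$d) != length(b$d))
    return(sign(length(a$d) - length(b$d)))
  for (i in rev(seq_along(a$d))) {
    if (a$d[i] != b$d[i]) return(sign(a$d[i] - b$d[i]))
  }
  0L
}

.big_sub <- function(a, b) {
  if (.big_cmp(a, b) < 0) stop("negative bigint result")
  n <- length(a$d)
  x <- a$d
  y <- c(b$d, numeric(n - length(b$d)))
  s <- x - y
  for (i in seq_len(n)) {
    if (s[i] < 0) {
      s[i] <- s[i] + .BIGBASE
      s[i + 1L] <- s[i + 1L] - 1
    }
  }
  .big(s)
}

.big_mul <- function(a, b) {
  na <- length(a$d); nb <- length(b$d)
  out <- numeric(na + nb)
  for (i in seq_len(na)) {
    carry <- 0
    ai <- a$d[i]
    for (j in seq_len(nb)) {
      t <- out[i + j - 1L] + ai * b$d[j] + carry
      carry <- floor(t / .BIGBASE)
      out[i + j - 1L] <- t - carry * .BIGBASE
    }
    k <- i + nb
    while (carry > 0) {
      t <- out[k] + carry
      carry <- floor(t / .BIGBASE)
      out[k] <- t - carry * .BIGBASE
      k <- k + 1L
    }
  }
  .big(out)
}

# exact division by a small positive integer (< 1e7); errors on remainder
.big_div_small <- function(a, s) {
  stopifnot(s >= 1, s < .BIGBASE)
  out <- numeric(length(a$d))
  rem <- 0
  for (i in rev(seq_along(a$d))) {
    cur <- rem * .BIGBASE + a$d[i]
    out[i] <- floor(cur / s)
    rem <- cur - out[i] * s
  }
  if (rem != 0) stop("inexact bigint division")
  .big(out)
}

.big_pow_small <- function(base, n) {
  out <- bigint(1)
  b <- bigint(base)
  for (k in seq_len(n)) out <- .big_mul(out, b)
  out
}

.big_fact <- function(n) {
  out <- bigint(1)
  for (k in seq_len(n)) out <- .big_mul(out, bigint(k))
  out
}

#' @export
as.character.bigint <- function(x, ...) {
  d <- rev(x$d)
  paste0(sprintf("%.0f", d[1]),
         paste(sprintf("%07.0f", d[-1]), collapse = ""))
}

#' @export
print.bigint <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}

#' @export
"*.bigint" <- function(e1, e2) .big_mul(e1, e2)

#' @export
"+.bigint" <- function(e1, e2) .big_add(e1, e2)

#' @export
"-.bigint" <- function(e1, e2) .big_sub(e1, e2)

#' @export
"==.bigint" <- function(e1, e2) .big_cmp(e1, e2) == 0L

#' Scientific notation for exact big integers
#'
#' Formats a [bigint()] as `m.mmm e E` at the requested number of
#' significant figures, rounding half to even on the decimal digits.
#'
#' @param x A `bigint` (or a non-negative double).
#' @param digits Significant figures (default 4).
#' @return A string such as `"5.225e8"`.
#' @examples
#' formatSci(spaceSize("DEG"))
#' @export
formatSci <- function(x, digits = 4L) {
  if (!inherits(x, "bigint")) x <- bigint(x)
  s <- as.character(x)
  expo <- nchar(s) - 1L
  # round the decimal string to `digits` significant figures, half-even
  if (nchar(s) > digits) {
    head <- as.numeric(substr(s, 1L, digits))
    restFirst <- as.integer(substr(s, digits + 1L, digits + 1L))
    restTail <- sub("0+$", "", substr(s, digits + 2L, nchar(s)))
    if (restFirst > 5L || (restFirst == 5L && nzchar(restTail))) {
      head <- head + 1
    } else if (restFirst == 5L && !nzchar(restTail)) {
      if (head %% 2 == 1) head <- head + 1   # ties to even
    }
    if (nchar(sprintf("%.0f", head)) > digits) { # carried over, 999 -> 1000
      head <- head / 10
      expo <- expo + 1L
    }
    s <- sprintf("%.0f", head)
  }
  mant <- if (nchar(s) > 1L)
    paste0(substr(s, 1L, 1L), ".", substr(s, 2L, nchar(s)))
  else s
  paste0(mant, "e", expo)
}

# surjections of n labeled items onto k labels, by inclusion-exclusion:
# sum_{i} (-1)^i C(k,i) (k-i)^n, accumulated as two non-negative bigints
.surjections <- function(n, k) {
  pos <- bigint(0); neg <- bigint(0)
  for (i in 0:k) {
    term <- .big_mul(bigint(choose(k, i)), .big_pow_small(k - i, n))
    if (i %% 2 == 0) pos <- .big_add(pos, term) else neg <- .big_add(neg, term)
  }
  .big_sub(pos, neg)
}

# surjections via the Stirling-number recurrence S(n,k) = k S(n-1,k) +
# S(n-1,k-1), times k!; an independent route used for cross-checking
.surjections_stirling <- function(n, k) {
  S <- vector("list", k + 1L)   # S[[j+1]] = S(row, j)
  for (j in 0:k) S[[j + 1L]] <- bigint(as.numeric(j == 0))
  for (row in seq_len(n)) {
    newS <- vector("list", k + 1L)
    newS[[1L]] <- bigint(as.numeric(row == 0))
    for (j in seq_len(k)) {
      newS[[j + 1L]] <- .big_add(.big_mul(bigint(j), S[[j + 1L]]), S[[j]])
    }
    S <- newS
  }
  .big_mul(S[[k + 1L]], .big_fact(k))
}

#' Exact size of a genetic-code model space
#'
#' Closed-form exact counts of the number of distinct codes each model can
#' produce, relative to the standard code's structure: \describe{
#'   \item{DEG}{independent permutations within each degeneracy class:
#'     3! 5! 1! 9! 2! = 522,547,200 (prints as 5.225e8);}
#'   \item{BLO}{all permutations of the 20 amino acids over the 20
#'     synonymous blocks: 20! (prints as 2.433e18);}
#'   \item{NUM}{multinomial assignments of the 61 codons into the standard
#'     per-amino-acid counts: 61! / prod(n_a!) (prints as 5.559e64);}
#'   \item{GEN}{surjections of 61 codons onto 20 amino acids by
#'     inclusion-exclusion (prints as 8.788e78).}
#' }
#'
#' @param model One of "DEG", "BLO", "NUM", "GEN".
#' @return A [bigint()].
#' @examples
#' formatSci(spaceSize("BLO"))
#' @export
spaceSize <- function(model = c("DEG", "BLO", "NUM", "GEN")) {
  model <- match.arg(model)
  switch(model,
    DEG = {
      out <- bigint(1)
      for (cl in .DEG_CLASSES) out <- .big_mul(out, .big_fact(length(cl)))
      out
    },
    BLO = .big_fact(20L),
    NUM = {
      out <- .big_fact(61L)
      for (n in .SGC_COUNTS)
        for (s in seq_len(n)) out <- .big_div_small(out, s)
      out
    },
    GEN = .surjections(61L, 20L)
  )
}

#' Exact number of genetic codes with 61 sense codons and 3 stops
#'
#' Surjections of the 64 codons onto 21 labels (20 amino acids plus stop),
#' counting every code that uses all amino acids and the stop signal with
#' no constraint on which codons are stops.  Prints as 1.51e84.
#'
#' @return A [bigint()].
#' @examples
#' formatSci(totalSpaceSize(), digits = 3)
#' @export
totalSpaceSize <- function() {
  .surjections(64L, 21L)
}
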