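# small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# run code with a temporarily seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible child seed below 2^31
child_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + 1103 * i) %% 2147483647
}

stopifnot_named <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# gradient of a 3D array with physical spacing; central differences inside,
# one-sided at the borders
grad3_r <- function(a, spacing) {
  d <- dim(a)
  g <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    denom <- (ip - im) * spacing[ax]
    denom[denom == 0] <- spacing[ax]
    if (ax == 1) {
      gi <- (a[ip, , , drop = FALSE] - a[im, , , drop = FALSE]) /
        array(denom, dim = d)
    } else if (ax == 2) {
      gi <- (a[, ip, , drop = FALSE] - a[, im, , drop = FALSE]) /
        aperm(array(denom, dim = d[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      gi <- (a[, , ip, drop = FALSE] - a[, , im, drop = FALSE]) /
        aperm(array(denom, dim = d[c(3, 1, 2)]), c(2, 3, 1))
    }
    g[[ax]] <- gi
  }
  g
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
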