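#' @keywords internal
"_PACKAGE"

# round half away from zero, elementwise (base round() is banker's rounding)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# shift a 3-D array along one axis by `by` voxels, zero-filling
shift3 <- function(a, axis, by) {
  if (by == 0L) return(a)
  d <- dim(a)
  out <- array(0, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0L) seq_len(n - by) else seq.int(1L - by, n)
  dst <- if (by > 0L) seq.int(1L + by, n) else seq_len(n + by)
  idx_src <- idx_dst <- rep(list(quote(expr = )), 3L)
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out_call <- as.call(c(list(quote(`[<-`), quote(out)), idx_dst,
                        list(as.call(c(list(quote(`[`), quote(a)), idx_src)))))
  eval(out_call)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
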