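#' Rarefaction of pan- and core-genome sizes
#'
#' For each sample size n and iteration, draws n individuals uniformly
#' without replacement and records the pan size (genes present in at least
#' one sampled individual) and core size (genes present in all sampled
#' individuals). Within an iteration a single random permutation is
#' accumulated, so each size-n prefix is a uniform sample of n individuals
#' and the whole curve costs one pass. Deterministic under `seed`.
#'
#' @param m presence matrix (genes x individuals).
#' @param iterations number of random orderings (default 200).
#' @param seed RNG seed.
#' @param sizes sample sizes to report; default `1:ncol(m)`. A stride can
#'   be used for very large cohorts.
#' @return list of class `rarefaction_result`: `pan`, `core` (iterations x
#'   sizes integer matrices), `summary` (per-n mean/sd), `sizes`, `seed`.
#' @export
rarefy <- function(m, iterations = 200L, seed = 1L, sizes = NULL) {
  m <- presence_as_matrix(m)
  n_ind <- ncol(m)
  if (n_ind < 1) stop("rarefaction needs at least one individual", call. = FALSE)
  if (iterations < 1) stop_config("iterations", "must be >= 1")
  sizes <- sort(unique(as.integer(sizes %||% seq_len(n_ind))))
  if (any(sizes < 1 | sizes > n_ind))
    stop_config("sizes", "must lie in 1..N individuals")
  pan <- matrix(0L, nrow = iterations, ncol = length(sizes),
                dimnames = list(NULL, sizes))
  core <- matrix(0L, nrow = iterations, ncol = length(sizes),
                 dimnames = list(NULL, sizes))
  withr::with_seed(seed, {
    for (it in seq_len(iterations)) {
      perm <- sample.int(n_ind)
      cum <- m[, perm, drop = FALSE]
      cum <- matrixCumsumRows(cum)
      pan[it, ] <- colSums(cum[, sizes, drop = FALSE] >= 1L)
      core[it, ] <- colSums(cum[, sizes, drop = FALSE] ==
                              matrix(sizes, nrow = nrow(m), ncol = length(sizes),
                                     byrow = TRUE))
    }
  })
  summary <- data.table(
    n = sizes,
    pan_mean = colMeans(pan), pan_sd = apply(pan, 2, sd),
    core_mean = colMeans(core), core_sd = apply(core, 2, sd))
  structure(list(pan = pan, core = core, summary = summary,
                 sizes = sizes, seed = seed),
            class = "rarefaction_result")
}

# row-wise cumulative sums of a genes x individuals matrix (genes stay rows)
matrixCumsumRows <- function(m) {
  if (ncol(m) <= 1) return(m)
  t(apply(m, 1L, cumsum))
}

#' Fit a saturation model to the mean pan curve
#'
#' Fits the bounded exponential P(n) = A - B exp(-n / tau) by nonlinear
#' least squares (A is the estimated total pan-genome size), plus Heaps'
#' power law P(n) = D n^gamma on n >= 2 via log-log regression. The pool is
#' called open when the largest observed mean pan size is still below 99%
#' of the fitted asymptote, or when the Heaps exponent exceeds 0.02.
#'
#' A bounded form is used because an estimated finite total is wanted; a
#' pure power law has no asymptote. An exactly flat curve short-circuits to
#' the degenerate fit (B = 0, A = observed constant).
#'
#' @param result a `rarefaction_result`.
#' @return list of class `pan_model_fit`: `asymptote` (A), `amplitude` (B),
#'   `rate` (tau), `heaps_gamma`, `heaps_D`, `openness` ("open"/"closed"),
#'   `converged`, `last_pan`.
#' @export
fit_pan_model <- function(result) {
  stopifnot(inherits(result, "rarefaction_result"))
  s <- result$summary
  if (nrow(s) < 4) stop("saturation fit needs >= 4 distinct sample sizes",
                        call. = FALSE)
  n <- s$n; y <- s$pan_mean
  last_pan <- y[length(y)]
  if (sd(y) == 0) {
    fit <- list(asymptote = last_pan, amplitude = 0, rate = Inf,
                heaps_gamma = 0, heaps_D = last_pan,
                openness = "closed", converged = TRUE, last_pan = last_pan)
    class(fit) <- "pan_model_fit"
    return(fit)
  }
  start <- list(A = max(y) + 0.05 * diff(range(y)),
                B = max(y) - min(y),
                tau = max(n) / 3)
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A - B * exp(-n / tau),
                      data = data.frame(n = n, y = y),
                      start = start,
                      lower = c(A = max(y), B = 0, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(nls_fit, "error"))
    stop(sprintf("saturation fit failed to converge: %s",
                 conditionMessage(nls_fit)), call. = FALSE)
  cf <- coef(nls_fit)
  hn <- n >= 2 & y > 0
  heaps <- lm(log(y[hn]) ~ log(n[hn]))
  gamma <- unname(coef(heaps)[2])
  D <- exp(unname(coef(heaps)[1]))
  open <- last_pan < 0.99 * cf[["A"]] || gamma > 0.02
  fit <- list(asymptote = cf[["A"]], amplitude = cf[["B"]], rate = cf[["tau"]],
              heaps_gamma = gamma, heaps_D = D,
              openness = if (open) "open" else "closed",
              converged = TRUE, last_pan = last_pan)
  class(fit) <- "pan_model_fit"
  fit
}

#' @export
print.pan_model_fit <- function(x, ...) {
  cat("<pan_model_fit>\n")
  cat(sprintf("  P(n) = A - B exp(-n/tau): A = %.1f, B = %.1f, tau = %.2f\n",
              x$asymptote, x$amplitude, x$rate))
  cat(sprintf("  Heaps gamma = %.4f; last observed pan = %.1f\n",
              x$heaps_gamma, x$last_pan))
  cat("  verdict:", x$openness, "\n")
  invisible(x)
}

#' Write / read a rarefaction report
#'
#' TSV with per-n mean/SD rows, preceded by `#fit` comment lines carrying
#' the saturation-fit summary (or `status=failed`). The reader restores
#' both parts.
#'
#' @param result a `rarefaction_result`.
#' @param fit a `pan_model_fit`, or `NULL` for a failed/absent fit.
#' @param path file path.
#' @return `write_rarefaction`: `path` invisibly; `read_rarefaction`: list
#'   with `summary` (data.table) and `fit` (named list).
#' @export
write_rarefaction <- function(result, fit, path) {
  header <- if (is.null(fit)) {
    "#fit status=failed"
  } else {
    sprintf("#fit status=ok asymptote=%.6g amplitude=%.6g rate=%.6g heaps_gamma=%.6g openness=%s",
            fit$asymptote, fit$amplitude, fit$rate, fit$heaps_gamma,
            fit$openness)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("n", "pan_mean", "pan_sd", "core_mean", "core_sd"),
                   collapse = "\t"), con)
  s <- result$summary
  writeLines(sprintf("%d\t%.6g\t%.6g\t%.6g\t%.6g",
                     s$n, s$pan_mean, s$pan_sd, s$core_mean, s$core_sd), con)
  invisible(path)
}

#' @rdname write_rarefaction
#' @export
read_rarefaction <- function(path) {
  lines <- readLines(path)
  fit_line <- lines[startsWith(lines, "#fit")]
  kv <- strsplit(sub("^#fit ", "", fit_line), " ")[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  fit <- setNames(lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  }), vapply(kv, `[`, "", 1))
  summary <- fread(text = lines[!startsWith(lines, "#")], sep = "\t",
                   header = TRUE)
  list(summary = summary, fit = fit)
}
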