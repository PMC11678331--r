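# Interpolation of mean/sd time courses and parametric resampling.

#' Densify a dataset by linear interpolation
#'
#' Inserts `n_intermediate` equally spaced interior time points between every
#' adjacent pair of observed sampling terms, linearly interpolating both the
#' mean and the s.d. of every gene. Observed points are kept unchanged, grids
#' stay identical across genes within a block, and a per-point `observed` flag
#' records provenance. Each series grows from `n` to
#' `n + n_intermediate * (n - 1)` points.
#'
#' @param ds An [ft_dataset()].
#' @param n_intermediate Number of interior points per observed interval
#'   (non-negative integer; default 3).
#' @return An object of class `c("ft_dense", "ft_dataset")`.
#' @export
#' @examples
#' ds <- generate_dataset(make_scenario("Ku_like_SD"))
#' dense <- interpolate(ds, n_intermediate = 3)
#' table(dense$data$observed)
interpolate <- function(ds, n_intermediate = 3) {
  stopifnot(inherits(ds, "ft_dataset"))
  n_intermediate <- as.integer(n_intermediate)
  if (length(n_intermediate) != 1 || is.na(n_intermediate) ||
      n_intermediate < 0) {
    stop("n_intermediate must be a single non-negative integer")
  }
  d <- ds$data
  blk <- .block_of(d$vernalization, d$daytime)
  pieces <- lapply(.BLOCKS, function(b) {
    db <- d[blk == b, , drop = FALSE]
    obs_t <- sort(unique(db$time_days))
    if (length(obs_t) < 2) stop("block ", b, ": need >= 2 points")
    new_t <- obs_t
    if (n_intermediate > 0) {
      interior <- unlist(lapply(seq_len(length(obs_t) - 1), function(i) {
        seq(obs_t[i], obs_t[i + 1],
            length.out = n_intermediate + 2)[-c(1, n_intermediate + 2)]
      }))
      new_t <- sort(c(obs_t, interior))
    }
    observed <- new_t %in% obs_t
    do.call(rbind, lapply(.ALL_GENES, function(g) {
      dg <- db[db$gene == g, , drop = FALSE]
      term <- rep("interp", length(new_t))
      term[observed] <- dg$term[match(new_t[observed], dg$time_days)]
      data.frame(
        vernalization = dg$vernalization[1],
        daytime = dg$daytime[1],
        term = term,
        time_days = new_t,
        gene = g,
        mean = stats::approx(dg$time_days, dg$mean, xout = new_t)$y,
        sd = stats::approx(dg$time_days, dg$sd, xout = new_t)$y,
        observed = observed,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- ds
  out$data <- do.call(rbind, pieces)
  out <- validate_ft_dataset(out)
  class(out) <- c("ft_dense", "ft_dataset")
  out
}

#' Draw resampled expression datasets
#'
#' Generates `n_samples` independent replicate datasets by sampling every
#' (block, gene, time) expression level from a normal distribution with the
#' mean and s.d. of the corresponding (dense) data point. Draws are
#' untruncated, so values may be negative. One global seed spawns a
#' per-replicate substream, making both the full ensemble and any individual
#' replicate reproducible.
#'
#' @param dense An [ft_dataset()] or the output of [interpolate()].
#' @param n_samples Number of replicates (>= 1); the reference analysis uses
#'   1000.
#' @param seed Integer seed for the ensemble.
#' @return An object of class `ft_resamples`: the reference point table plus a
#'   `points x genes x replicates` array of sampled values.
#' @export
#' @examples
#' dense <- interpolate(generate_dataset(make_scenario("Ku_like_SD")), 3)
#' rs <- resample(dense, n_samples = 10, seed = 1)
#' dim(rs$values)
resample <- function(dense, n_samples, seed) {
  stopifnot(inherits(dense, "ft_dataset"))
  n_samples <- as.integer(n_samples)
  if (length(n_samples) != 1 || is.na(n_samples) || n_samples < 1) {
    stop("n_samples must be a positive integer")
  }
  mats <- .as_matrices(dense)
  npts <- nrow(mats$mean)
  set.seed(as.integer(seed))
  substreams <- sample.int(.Machine$integer.max, n_samples)
  values <- array(NA_real_, dim = c(npts, length(.ALL_GENES), n_samples),
                  dimnames = list(NULL, .ALL_GENES, NULL))
  mu <- as.vector(mats$mean)
  sigma <- as.vector(mats$sd)
  for (r in seq_len(n_samples)) {
    set.seed(substreams[r])
    values[, , r] <- mu + sigma * stats::rnorm(length(mu))
  }
  structure(
    list(points = mats$points, mean = mats$mean, sd = mats$sd,
         values = values, n_samples = n_samples, seed = as.integer(seed),
         line = dense$line, photoperiod = dense$photoperiod),
    class = "ft_resamples"
  )
}

#' @export
print.ft_resamples <- function(x, ...) {
  cat("<ft_resamples> ", x$n_samples, " replicates x ", nrow(x$points),
      " points x 5 genes (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Extract one replicate as a dataset
#'
#' Returns replicate `r` of a resampled ensemble as an `ft_dataset` whose
#' `mean` column holds the sampled expression levels (possibly negative) and
#' whose `sd` column carries the reference data s.d. used in cost
#' denominators.
#'
#' @param rs An [resample()] ensemble.
#' @param r Replicate index in `1..n_samples`.
#' @return An [ft_dataset()] (not re-checked for non-negative means).
#' @export
replicate_dataset <- function(rs, r) {
  stopifnot(inherits(rs, "ft_resamples"))
  r <- as.integer(r)
  if (r < 1 || r > rs$n_samples) stop("replicate index out of range")
  p <- rs$points
  rows <- do.call(rbind, lapply(.ALL_GENES, function(g) {
    data.frame(
      vernalization = p$vernalization, daytime = p$daytime, term = p$term,
      time_days = p$time_days, gene = g,
      mean = rs$values[, g, r], sd = rs$sd[, g],
      stringsAsFactors = FALSE
    )
  }))
  ft_dataset(rs$line, rs$photoperiod, rows, require_nonneg_mean = FALSE)
}
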