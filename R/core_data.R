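# Domain constants and the long-form expression dataset container.

#' Gene and condition vocabulary
#'
#' The predictor universe is exactly the four FT-like florigen genes of
#' *Lupinus angustifolius*; `AGL8` (the *AP1*/*FUL* ortholog marking floral
#' induction) is always the regression target and never a predictor.
#'
#' @format `ft_genes()` returns `c("FTc1", "FTa1", "FTc2", "FTa2")`;
#'   `target_gene()` returns `"AGL8"`; `condition_blocks()` returns the four
#'   vernalization-by-daytime block labels in canonical order.
#' @name vocabulary
NULL

.FT_GENES <- c("FTc1", "FTa1", "FTc2", "FTa2")
.TARGET <- "AGL8"
.ALL_GENES <- c(.FT_GENES, .TARGET)
.VERN <- c("V", "N")
.DAYTIME <- c("morning", "evening")
.BLOCKS <- c("V.morning", "V.evening", "N.morning", "N.evening")
.PHOTOPERIODS <- c("SD_8h", "LD_16h")

#' @rdname vocabulary
#' @export
ft_genes <- function() .FT_GENES

#' @rdname vocabulary
#' @export
target_gene <- function() .TARGET

#' @rdname vocabulary
#' @export
condition_blocks <- function() .BLOCKS

# Display-only clock times for the two sampling moments of each photoperiod.
.daytime_clock <- function(photoperiod) {
  if (photoperiod == "SD_8h") c(morning = "9 A.M.", evening = "3 P.M.")
  else c(morning = "7 A.M.", evening = "6 P.M.")
}

.block_of <- function(vernalization, daytime) {
  factor(paste(vernalization, daytime, sep = "."), levels = .BLOCKS)
}

#' Construct an expression dataset for one line and photoperiod
#'
#' An `ft_dataset` holds qRT-PCR summary data (mean and s.d. of relative
#' expression per sampling term) for all five genes in all four
#' vernalization-by-daytime condition blocks of one (line, photoperiod)
#' combination -- the unit on which models are fitted.
#'
#' @param line Character label for the plant line (e.g. `"Ku"`, `"Pal"`,
#'   `"ku"`).
#' @param photoperiod One of `"SD_8h"` or `"LD_16h"`.
#' @param data A data frame with columns `vernalization` (`"V"`/`"N"`),
#'   `daytime` (`"morning"`/`"evening"`), `term` (sampling-term label),
#'   `time_days` (days since the first sampling term), `gene`, `mean`, `sd`.
#' @param require_nonneg_mean Should negative means be rejected? Observed
#'   relative expression is non-negative; resampled values may not be.
#'
#' @return An object of class `ft_dataset` with rows in canonical
#'   (block, gene, time) order.
#' @export
#' @examples
#' cfg <- make_scenario("Ku_like_SD")
#' ds <- generate_dataset(cfg)
#' head(ds$data)
ft_dataset <- function(line, photoperiod, data, require_nonneg_mean = TRUE) {
  photoperiod <- match.arg(photoperiod, .PHOTOPERIODS)
  ds <- structure(
    list(line = as.character(line), photoperiod = photoperiod,
         data = as.data.frame(data)),
    class = "ft_dataset"
  )
  validate_ft_dataset(ds, require_nonneg_mean = require_nonneg_mean)
}

.DATA_COLS <- c("vernalization", "daytime", "term", "time_days",
                "gene", "mean", "sd")

#' Validate an expression dataset
#'
#' Checks the invariants the fitting machinery relies on: all five genes
#' present in all four condition blocks, identical strictly increasing time
#' grids across genes within a block, at least two sampling terms per series,
#' and non-negative standard deviations. Rows are put into canonical
#' (block, gene, time) order.
#'
#' @param ds An `ft_dataset`.
#' @param require_nonneg_mean Reject negative means (default `TRUE`).
#' @return The validated, canonically ordered dataset (invisibly its input).
#' @export
validate_ft_dataset <- function(ds, require_nonneg_mean = TRUE) {
  d <- ds$data
  missing_cols <- setdiff(.DATA_COLS, names(d))
  if (length(missing_cols) > 0) {
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(d) == 0) {
    ds$data <- d[, .DATA_COLS]
    return(ds)
  }
  if (!all(d$gene %in% .ALL_GENES)) {
    stop("unknown gene label(s): ",
         paste(setdiff(unique(d$gene), .ALL_GENES), collapse = ", "))
  }
  if (!all(d$vernalization %in% .VERN)) stop("vernalization must be 'V' or 'N'")
  if (!all(d$daytime %in% .DAYTIME)) {
    stop("daytime must be 'morning' or 'evening'")
  }
  if (any(!is.finite(d$mean)) || any(!is.finite(d$sd)) ||
      any(!is.finite(d$time_days))) {
    stop("mean, sd and time_days must be finite")
  }
  if (any(d$sd < 0)) stop("negative sd")
  if (require_nonneg_mean && any(d$mean < 0)) {
    stop("negative expression mean")
  }
  if (any(d$time_days < 0)) stop("negative time_days")

  blk <- .block_of(d$vernalization, d$daytime)
  gene <- factor(d$gene, levels = .ALL_GENES)
  d <- d[order(blk, gene, d$time_days), , drop = FALSE]
  rownames(d) <- NULL
  blk <- .block_of(d$vernalization, d$daytime)

  for (b in .BLOCKS) {
    db <- d[blk == b, , drop = FALSE]
    if (nrow(db) == 0) stop("missing condition block: ", b)
    grids <- split(db$time_days, factor(db$gene, levels = .ALL_GENES))
    if (any(vapply(grids, length, 1L) == 0)) {
      stop("block ", b, " is missing gene(s): ",
           paste(names(grids)[vapply(grids, length, 1L) == 0], collapse = ", "))
    }
    ref <- grids[[.TARGET]]
    if (length(ref) < 2) stop("block ", b, " has fewer than 2 sampling terms")
    if (any(diff(ref) <= 0)) {
      stop("block ", b, ": time_days not strictly increasing")
    }
    same <- vapply(grids, function(g) length(g) == length(ref) &&
                     isTRUE(all.equal(g, ref)), logical(1))
    if (!all(same)) {
      stop("block ", b, ": time grids differ across genes (",
           paste(names(grids)[!same], collapse = ", "), ")")
    }
  }
  ds$data <- d[, c(.DATA_COLS, intersect("observed", names(d)))]
  ds
}

#' @export
print.ft_dataset <- function(x, ...) {
  n_terms <- length(unique(x$data$time_days[
    x$data$gene == .TARGET &
      .block_of(x$data$vernalization, x$data$daytime) == .BLOCKS[1]]))
  cat("<ft_dataset> line ", x$line, ", photoperiod ", x$photoperiod,
      ": 5 genes x 4 blocks, ", n_terms, " points per series\n", sep = "")
  invisible(x)
}

#' Read an expression dataset from long-form CSV
#'
#' The CSV dialect is comma-separated UTF-8 with a `.` decimal mark and one
#' row per (condition, gene, sampling term); required columns are `line`,
#' `photoperiod`, `vernalization`, `daytime`, `term`, `time_days`, `gene`,
#' `mean`, `sd`. Only rows matching the requested line and photoperiod are
#' retained, and all dataset invariants are checked.
#'
#' @param path Path to the CSV file.
#' @param line Line label to select.
#' @param photoperiod Photoperiod to select, `"SD_8h"` or `"LD_16h"`.
#' @return A validated [ft_dataset()].
#' @export
read_dataset <- function(path, line, photoperiod) {
  photoperiod <- match.arg(photoperiod, .PHOTOPERIODS)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("line", "photoperiod", .DATA_COLS)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  sel <- raw$line == line & raw$photoperiod == photoperiod
  if (!any(sel)) {
    stop("no rows for line '", line, "' and photoperiod '", photoperiod, "'")
  }
  ft_dataset(line, photoperiod, raw[sel, .DATA_COLS, drop = FALSE])
}

#' Write an expression dataset to long-form CSV
#'
#' Rows are emitted in canonical (block, gene, time) order so repeated writes
#' of the same dataset are byte-identical. Numeric values are written with 15
#' significant digits; `read_dataset(write_dataset(ds))` reproduces the
#' numeric payload to that precision.
#'
#' @param ds An [ft_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  d <- ds$data[, .DATA_COLS, drop = FALSE]
  out <- data.frame(line = rep(ds$line, nrow(d)),
                    photoperiod = rep(ds$photoperiod, nrow(d)),
                    d, stringsAsFactors = FALSE)
  for (col in c("time_days", "mean", "sd")) {
    out[[col]] <- formatC(d[[col]], digits = 15, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Wide matrices aligned to a canonical point table: one row per
# (block, time), one column per gene. Relies on canonical row order and the
# shared within-block grid guaranteed by validation.
.as_matrices <- function(ds) {
  d <- ds$data
  blk <- .block_of(d$vernalization, d$daytime)
  tgt <- d$gene == .TARGET
  points <- data.frame(
    block = blk[tgt],
    vernalization = d$vernalization[tgt],
    daytime = d$daytime[tgt],
    term = d$term[tgt],
    time_days = d$time_days[tgt],
    stringsAsFactors = FALSE
  )
  get <- function(col) {
    m <- vapply(.ALL_GENES, function(g) d[[col]][d$gene == g],
                numeric(nrow(points)))
    colnames(m) <- .ALL_GENES
    m
  }
  out <- list(points = points, mean = get("mean"), sd = get("sd"))
  if ("observed" %in% names(d)) out$observed <- d$observed[tgt]
  out
}
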