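#' Cotransporter expression series
#'
#' Immunofluorescence expression of one chloride cotransporter (NKCC1 or
#' KCC2) in one genotype, quantified as percent of a reference condition at
#' a series of culture ages (DIVs). Each point carries the mean, its SEM and
#' the number of cultures.
#'
#' @param genotype Genotype label (e.g. `"WT"`, `"Lgdel"`, `"Dgcr8"`).
#' @param transporter `"NKCC1"` or `"KCC2"`.
#' @param div Culture ages in days in vitro; must be strictly increasing
#'   (points are sorted before checking).
#' @param mean_pct Mean expression, percent of reference (> 0).
#' @param sem_pct Standard error of the mean, same scale.
#' @param n Number of cultures per point (>= 1).
#' @return An object of class `expression_series` with a `points` data frame
#'   sorted by `div`.
#' @export
expression_series <- function(genotype, transporter, div, mean_pct,
                              sem_pct = rep(0, length(div)),
                              n = rep(1L, length(div))) {
  transporter <- match.arg(transporter, c("NKCC1", "KCC2"))
  pts <- data.frame(div = as.numeric(div), mean_pct = as.numeric(mean_pct),
                    sem_pct = as.numeric(sem_pct), n = as.integer(n))
  pts <- pts[order(pts$div), , drop = FALSE]
  rownames(pts) <- NULL
  if (any(duplicated(pts$div))) stop("duplicate DIV in expression series")
  if (any(pts$mean_pct <= 0)) stop("mean_pct must be > 0")
  if (any(pts$n < 1L)) stop("n must be >= 1")
  structure(list(genotype = genotype, transporter = transporter,
                 points = pts),
            class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  cat(sprintf("%s %s expression, %d DIVs (%s)\n", x$genotype, x$transporter,
              nrow(x$points), paste(x$points$div, collapse = ", ")))
  invisible(x)
}

#' Read a cotransporter expression table
#'
#' Reads a CSV with header `genotype,transporter,div,mean_pct,sem_pct,n` and
#' returns one [expression_series()] per (genotype, transporter) pair, with
#' points sorted by DIV. Duplicate (genotype, transporter, div) rows and
#' non-positive means are rejected.
#'
#' @param path Path to the CSV file.
#' @return Named list of `expression_series`; names are
#'   `"<genotype>.<transporter>"`.
#' @export
read_expression_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("genotype", "transporter", "div", "mean_pct", "sem_pct", "n")
  if (!all(needed %in% names(tab))) {
    stop("expression table must have columns: ",
         paste(needed, collapse = ", "))
  }
  if (any(duplicated(tab[, c("genotype", "transporter", "div")]))) {
    stop("duplicate (genotype, transporter, div) rows")
  }
  key <- interaction(tab$genotype, tab$transporter, drop = TRUE)
  out <- lapply(split(tab, key), function(d) {
    expression_series(d$genotype[1], d$transporter[1], d$div, d$mean_pct,
                      d$sem_pct, d$n)
  })
  out[order(names(out))]
}

#' Read a treatment-timeline MFR table
#'
#' Reads a CSV with header `genotype,condition,timepoint,mfr_pct,sem_pct`
#' holding baseline-normalized mean-firing-rate trajectories (percent of
#' baseline, baseline = 100). Every (genotype, condition) group must contain
#' a row with `mfr_pct == 100` (the baseline).
#'
#' @param path Path to the CSV file.
#' @return A data frame with the five columns above.
#' @export
read_timeline_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("genotype", "condition", "timepoint", "mfr_pct", "sem_pct")
  if (!all(needed %in% names(tab))) {
    stop("timeline table must have columns: ", paste(needed, collapse = ", "))
  }
  key <- interaction(tab$genotype, tab$condition, drop = TRUE)
  has_base <- vapply(split(tab$mfr_pct, key),
                     function(v) any(v == 100), logical(1))
  if (!all(has_base)) {
    stop("missing baseline (mfr_pct == 100) row for: ",
         paste(names(has_base)[!has_base], collapse = ", "))
  }
  tab
}
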