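#' Read a per-study dataset from CSV/TSV
#'
#' Strict reader for the three supported layouts:
#' \describe{
#'   \item{`effects`}{columns `study`, `yi`, `vi`; any further numeric
#'     columns are kept as covariates.}
#'   \item{`two_group`}{columns `study`, `d`, `n1`, `n2`; converted to
#'     Hedges' g via [hedges_g()].}
#'   \item{`fourfold`}{columns `study`, `a`, `b`, `c`, `d`; converted to log
#'     odds ratios via [log_odds_ratio()].}
#' }
#' The reader never coerces silently: a missing column, a non-numeric cell,
#' a duplicate study id or a nonpositive `vi` each raise an error naming the
#' offending row and column.
#'
#' @param path file path; `.tsv`/`.tab` files are read tab-separated,
#'   anything else comma-separated.
#' @param kind input layout, see above.
#' @param columns optional named character vector remapping canonical names
#'   to file column names, e.g. `c(yi = "effect", vi = "var")`.
#' @return data.frame with columns `study`, `yi`, `vi` plus any covariates;
#'   attributes `scale` (effect-size scale) and `source` (the path).
#' @export
read_meta_data <- function(path, kind = c("effects", "two_group", "fourfold"),
                           columns = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  required <- switch(kind,
                     effects   = c("study", "yi", "vi"),
                     two_group = c("study", "d", "n1", "n2"),
                     fourfold  = c("study", "a", "b", "c", "d"))
  have <- required
  if (!is.null(columns)) {
    have[match(names(columns), required)] <- columns
  }
  missing_cols <- have[!have %in% names(raw)]
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(col_file, col_name) {
    x <- suppressWarnings(as.numeric(raw[[col_file]]))
    bad <- which(is.na(x) & !is.na(raw[[col_file]]) | is.na(raw[[col_file]]))
    if (length(bad)) {
      stop("non-numeric value in column '", col_name, "', row ", bad[1],
           " of ", path, call. = FALSE)
    }
    x
  }
  study <- raw[[have[1]]]
  if (anyDuplicated(study)) {
    stop("duplicate study id '", study[duplicated(study)][1], "' in ", path,
         call. = FALSE)
  }
  if (nrow(raw) < 2) stop("fewer than 2 studies in ", path, call. = FALSE)

  extras <- setdiff(names(raw), c(have, "scale"))
  covs <- if (length(extras)) {
    as.data.frame(lapply(stats::setNames(extras, extras),
                         function(cl) num(cl, cl)),
                  check.names = FALSE)
  } else NULL

  out <- switch(kind,
    effects = {
      yi <- num(have[2], "yi"); vi <- num(have[3], "vi")
      bad <- which(vi <= 0)
      if (length(bad)) {
        stop("nonpositive vi in row ", bad[1], " of ", path, call. = FALSE)
      }
      data.frame(study = study, yi = yi, vi = vi, scale = "raw",
                 stringsAsFactors = FALSE)
    },
    two_group = cbind(study = study,
                      hedges_g(num(have[2], "d"), num(have[3], "n1"),
                               num(have[4], "n2"))),
    fourfold = cbind(study = study,
                     log_odds_ratio(num(have[2], "a"), num(have[3], "b"),
                                    num(have[4], "c"), num(have[5], "d")))
  )
  if (!is.null(covs)) out <- cbind(out, covs)
  attr(out, "scale") <- out$scale[1]
  attr(out, "source") <- path
  out
}

#' Write an effect-size table to CSV
#'
#' @param x data.frame with at least `study`, `yi`, `vi` (e.g. from
#'   [read_meta_data()] or the effect-size converters with a study column).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_sizes <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

results_table <- function(x) {
  if (inherits(x, "meta_analysis")) {
    tab <- as.data.frame(x)
    tab$term <- "intercept"
    tab[, c("method", "term", setdiff(names(tab), c("method", "term")))]
  } else if (inherits(x, "meta_regression")) {
    tab <- rbind(x$conventional, x$hk)
    tab$tau2 <- x$tau2$tau2
    tab
  } else {
    stop("unsupported results object of class ", class(x)[1], call. = FALSE)
  }
}

#' Serialize analysis results
#'
#' Writes a `meta_analysis` or `meta_regression` result as JSON (full
#' floating precision; parsing it back reproduces every numeric field
#' bit-exactly), TSV (one row per method x coefficient, full precision), or
#' the aligned text layout of the print methods (rounded to 3 decimals).
#'
#' @param x a `meta_analysis` or `meta_regression` object.
#' @param path destination file, or `NULL` to return the serialized text.
#' @param format `"json"`, `"tsv"` or `"text"`.
#' @return The serialized character value, invisibly when written to a file.
#' @export
write_meta_results <- function(x, path = NULL,
                               format = c("json", "tsv", "text")) {
  format <- match.arg(format)
  txt <- switch(format,
    json = as.character(jsonlite::toJSON(results_table(x), dataframe = "rows",
                                         digits = I(17), na = "null",
                                         auto_unbox = TRUE, pretty = TRUE)),
    tsv = {
      con <- textConnection("out", "w", local = TRUE)
      utils::write.table(results_table(x), con, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      close(con)
      paste0(paste(out, collapse = "\n"), "\n")
    },
    text = paste0(paste(utils::capture.output(print(x)), collapse = "\n"), "\n")
  )
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Write small example datasets
#'
#' Emits two tiny CSV fixtures generated from the random-effects simulator
#' with fixed seeds: an effect-size table (`effects.csv`, with one numeric
#' covariate) and a 2x2-count table (`fourfold.csv`).  Useful for trying the
#' readers and the command-line interface without external data.
#'
#' @param dir destination directory (created if needed).
#' @param seed base seed for the generator.
#' @return Character vector of the paths written.
#' @export
write_example_data <- function(dir, seed = 2026L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- simulation_spec(n = 12, mu = 0.3, tau2 = 0.1,
                        within_variances = function(n) stats::runif(n, 0.05, 0.3),
                        seed = seed)
  d <- generate_meta_dataset(sp, 1)
  eff <- data.frame(study = paste0("s", seq_len(12)),
                    yi = round(d$yi, 6), vi = round(d$vi, 6),
                    dose = rep(c(0, 1), each = 6))
  p1 <- file.path(dir, "effects.csv")
  utils::write.csv(eff, p1, row.names = FALSE, quote = FALSE)

  set.seed(stream_seed(seed, 2))
  m <- 8
  n_arm <- sample(50:200, m, replace = TRUE)
  p_ctl <- stats::runif(m, 0.1, 0.3)
  p_trt <- p_ctl * exp(stats::rnorm(m, -0.4, 0.3))
  ff <- data.frame(study = paste0("trial", seq_len(m)),
                   a = stats::rbinom(m, n_arm, p_trt),
                   b = NA, c = stats::rbinom(m, n_arm, p_ctl), d = NA)
  ff$b <- n_arm - ff$a
  ff$d <- n_arm - ff$c
  p2 <- file.path(dir, "fourfold.csv")
  utils::write.csv(ff, p2, row.names = FALSE, quote = FALSE)
  c(p1, p2)
}
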