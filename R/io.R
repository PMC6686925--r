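# Delimited-table IO and the per-SNP scan used by the command-line entry
# point. Input is a plain TSV/CSV with a header; column roles (phenotype,
# genotype, covariates) are named by the caller.

#' Read a subject-level table
#'
#' Reads a delimited text file (tab or comma; auto-detected from the header
#' line unless `delim` is given) with one row per subject. Missing-value
#' tokens (empty cell, `NA`, `.`) are detected and reported as an error
#' naming the offending rows, since the model has no missing-data path.
#'
#' @param path File path.
#' @param delim Optional delimiter (`"\t"` or `","`); auto-detected by
#'   default.
#' @return A tibble.
#' @export
read_subject_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    head_lines <- readLines(path, n = 50L)
    header <- head_lines[!startsWith(head_lines, "#")][1]
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  tb <- readr::read_delim(path, delim = delim, na = c("", "NA", "."),
                          comment = "#", show_col_types = FALSE,
                          trim_ws = TRUE)
  bad <- which(!stats::complete.cases(tb))
  if (length(bad)) {
    stop("missing values in rows: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10),
         call. = FALSE)
  }
  message(sprintf("read %d rows x %d columns from %s", nrow(tb), ncol(tb),
                  path))
  tb
}

#' Test several genotype columns against one ordinal phenotype
#'
#' Runs the latent-variable test (and optionally the probit/logit
#' comparators) once per genotype column against a shared phenotype and
#' covariate set — the typical multi-SNP layout with one additively coded
#' SNP (0/1/2) per column. Raw p-values are reported together with a
#' Bonferroni-adjusted column across the genotype columns tested.
#'
#' @param data A data frame, one row per subject.
#' @param genotypes Character vector of genotype column names.
#' @param phenotype Phenotype column name.
#' @param covariates Covariate column names; defaults to all remaining
#'   columns.
#' @param methods Subset of `c("lvm", "probit", "logit")`.
#' @return A tibble with one row per (genotype column, method): estimates,
#'   `statistic`, `p.value`, `p.bonferroni`, `converged`, `n`.
#' @export
lvm_scan <- function(data, genotypes, phenotype = "y", covariates = NULL,
                     methods = c("lvm", "probit", "logit")) {
  methods <- match.arg(methods, several.ok = TRUE)
  data <- as.data.frame(data)
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c(genotypes, phenotype))
  }
  out <- purrr::map_dfr(genotypes, function(gcol) {
    purrr::map_dfr(methods, function(m) {
      res <- if (m == "lvm") {
        fit <- tryCatch(
          lvm_test(data, genotype = gcol, phenotype = phenotype,
                   covariates = covariates),
          error = function(e) NULL)
        if (is.null(fit)) {
          tibble::tibble(estimate = NA_real_, statistic = NA_real_,
                         p.value = NA_real_, converged = FALSE,
                         n = nrow(data))
        } else {
          tibble::tibble(estimate = fit$rho_hat, statistic = fit$TW,
                         p.value = fit$p_value, converged = fit$converged,
                         n = fit$n)
        }
      } else {
        fit <- ordinal_reg_test(data, model = m, genotype = gcol,
                                phenotype = phenotype,
                                covariates = covariates)
        tibble::tibble(estimate = fit$beta_g, statistic = fit$z,
                       p.value = fit$p_value, converged = fit$converged,
                       n = fit$n)
      }
      dplyr::bind_cols(tibble::tibble(genotype = gcol, method = m), res)
    })
  })
  dplyr::mutate(
    dplyr::group_by(out, .data$method),
    p.bonferroni = pmin(1, .data$p.value * length(genotypes))) |>
    dplyr::ungroup()
}

#' Write a result table as TSV or JSON
#'
#' Serializes a result tibble with a small metadata header: package
#' version, seed (if any) and a config echo. TSV output carries the
#' metadata as `#`-prefixed comment lines; JSON output nests it under
#' `meta`.
#'
#' @param results A data frame of results.
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   anything else TSV).
#' @param seed Optional seed to record.
#' @param config Optional named list echoed into the metadata.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(results, path, seed = NULL, config = NULL) {
  meta <- c(list(package = "ordlvm",
                 version = as.character(utils::packageVersion("ordlvm")),
                 date = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
            if (!is.null(seed)) list(seed = seed),
            if (!is.null(config)) list(config = config))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(meta = meta, results = results), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    hdr <- vapply(seq_along(meta), function(i) {
      sprintf("# %s: %s", names(meta)[i],
              paste(deparse(meta[[i]], width.cutoff = 500), collapse = " "))
    }, character(1))
    writeLines(hdr, path)
    suppressWarnings(readr::write_tsv(results, path, append = TRUE,
                                      col_names = TRUE))
  }
  invisible(path)
}
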