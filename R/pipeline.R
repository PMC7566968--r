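#' Run the full comparative analysis
#'
#' Orchestrates the three study questions end to end on one dataset:
#' read and align inputs, quantify phylogenetic signal for each trait
#' ([signal_summary()]), fit the environmental PCA and attach PC scores
#' ([env_pca()], [add_pca_scores()]), run the batch of bivariate PGLS
#' regressions ([pgls_batch()]), fit the 10%/90% PQR boundaries per panel
#' and classify the threatened species against them
#' ([fit_pqr_boundary()], [classify_species()]).  The pipeline is a pure
#' function of its inputs and configuration: rerunning with the same
#' config yields an identical report.
#'
#' @param config a list, or the path to a YAML file, with elements:
#'   \describe{
#'     \item{tree}{path to a Newick file (or omit and pass `data`).}
#'     \item{table}{path to the species trait table; `sep`, `na_token`
#'       optional.}
#'     \item{traits}{trait columns for the signal stage (default
#'       `c("p50", "pn")`).}
#'     \item{pca}{list: `vars` (default the six environmental variables),
#'       `fit_on` (default `"all"`).}
#'     \item{pgls}{list with `panels`: data.frame(`response`,
#'       `predictor`, `transform`, `standardize`) and `subset` (default
#'       `"non_threatened"`).}
#'     \item{pqr}{list with `panels`: data.frame(`response`,
#'       `predictor`), `taus` (default `c(0.1, 0.9)`) and `subset`.}
#'   }
#' @param data optionally, an `"ecophylo_data"` object instead of file
#'   inputs.
#' @return an object of class `"ecophylo_report"`: `signal`, `pca`,
#'   `pgls`, `pqr` (list of boundaries), `classification`, `warnings`,
#'   `config_digest`.
#' @export
run_full_analysis <- function(config, data = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  warn <- character()
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  if (is.null(data)) {
    if (is.null(config$tree) || is.null(config$table))
      stop("config must name 'tree' and 'table' files (or pass data=)")
    tree <- collect(read_newick(config$tree))
    records <- collect(read_species_table(
      config$table, sep = config$sep %||% ",",
      na_token = config$na_token %||% "NA"))
    data <- collect(align_tree_and_table(tree, records))
  }
  traits <- config$traits %||% c("p50", "pn")
  signal <- collect(signal_summary(data, traits))
  pca_cfg <- config$pca %||% list()
  pca <- collect(env_pca(data,
                         vars = pca_cfg$vars %||% c("latitude", "altitude",
                                                    "mat", "map", "mtcm",
                                                    "wd"),
                         fit_on = pca_cfg$fit_on %||% "all"))
  data <- add_pca_scores(data, pca)
  pgls_cfg <- config$pgls %||% list()
  panels <- pgls_cfg$panels
  if (is.null(panels)) {
    env_vars <- pca$vars
    panels <- data.frame(
      response = rep(traits[1], length(env_vars) + 2L),
      predictor = c(env_vars, "pc1", "pc2"),
      transform = "none", standardize = TRUE,
      stringsAsFactors = FALSE)
  }
  panels <- as.data.frame(panels, stringsAsFactors = FALSE)
  slope_table <- collect(pgls_batch(data, panels,
                                    subset = pgls_cfg$subset %||%
                                      "non_threatened"))
  pqr_cfg <- config$pqr %||% list()
  pqr_panels <- pqr_cfg$panels
  if (is.null(pqr_panels))
    pqr_panels <- data.frame(response = traits[1], predictor = "pc2",
                             stringsAsFactors = FALSE)
  pqr_panels <- as.data.frame(pqr_panels, stringsAsFactors = FALSE)
  taus <- pqr_cfg$taus %||% c(0.10, 0.90)
  boundaries <- list()
  classification <- data.frame()
  focal <- data$data[data$data$status == "threatened" &
                       !is.na(data$data$status), , drop = FALSE]
  for (i in seq_len(nrow(pqr_panels))) {
    bd <- collect(fit_pqr_boundary(data, pqr_panels$response[i],
                                   pqr_panels$predictor[i], taus = taus,
                                   subset = pqr_cfg$subset %||%
                                     "non_threatened"))
    key <- paste(pqr_panels$response[i], pqr_panels$predictor[i],
                 sep = "~")
    boundaries[[key]] <- bd
    ok <- !is.na(focal[[pqr_panels$response[i]]]) &
      !is.na(focal[[pqr_panels$predictor[i]]])
    if (any(ok)) {
      cl <- classify_species(bd, focal[ok, , drop = FALSE])
      cl <- cbind(panel = key, cl)
      classification <- rbind(classification, cl)
    }
  }
  structure(list(signal = signal, pca = pca, pgls = slope_table,
                 pqr = boundaries, classification = classification,
                 warnings = warn,
                 config_digest = paste(utils::capture.output(
                   utils::str(config)), collapse = "\n")),
            class = "ecophylo_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ecophylo_report <- function(x, ...) {
  cat("== Phylogenetic signal ==\n")
  print(x$signal, digits = 4, row.names = FALSE)
  cat("\n== PGLS slopes ==\n")
  print(x$pgls, digits = 4, row.names = FALSE)
  cat("\n== PQR classification of threatened species ==\n")
  if (nrow(x$classification))
    print(x$classification[, c("panel", "species", "class")],
          row.names = FALSE)
  else cat("(no threatened species to classify)\n")
  if (length(x$warnings))
    cat("\n", length(x$warnings), "warning(s) collected; see $warnings\n")
  invisible(x)
}

#' Write a report's tables to a directory
#'
#' Emits delimited text tables (signal, PGLS slopes, PCA loadings and
#' scores, PQR boundary lines, classifications) and a machine-readable
#' JSON summary.  Timestamps are deliberately excluded so regeneration
#' from identical inputs is byte-identical.
#'
#' @param report an `"ecophylo_report"`.
#' @param dir output directory.
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ecophylo_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    path
  }
  files <- c(
    wt(report$signal, "signal.tsv"),
    wt(report$pgls, "pgls_slopes.tsv"),
    wt(data.frame(variable = rownames(report$pca$loadings),
                  report$pca$loadings[, 1:2],
                  check.names = FALSE), "pca_loadings.tsv"),
    wt(report$pca$scores, "pca_scores.tsv"),
    wt(do.call(rbind, lapply(names(report$pqr), function(k)
      cbind(panel = k, report$pqr[[k]]$lines))), "pqr_boundaries.tsv"))
  if (nrow(report$classification))
    files <- c(files, wt(report$classification, "classification.tsv"))
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    signal = report$signal, pgls = report$pgls,
    pca_variance_explained = report$pca$variance_explained,
    classification = report$classification,
    warnings = report$warnings),
    summary_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(report$warnings, file.path(dir, "warnings.txt"))
  invisible(c(files, summary_path))
}
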