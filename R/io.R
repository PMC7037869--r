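#' Read a labeled numeric matrix from CSV
#'
#' The interchange convention for all matrices in this package: UTF-8,
#' comma-separated, '.' decimal separator, first row = column labels, first
#' column = row labels. Every cell must parse as a number; empty cells,
#' ragged rows and duplicate labels are errors.
#'
#' @param path file path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!ncol(df) || !nrow(df)) stop("empty matrix file: ", path)
  rn <- df[[1]]
  if (anyDuplicated(rn))
    stop("duplicate row label: ", rn[duplicated(rn)][1])
  cn <- colnames(df)[-1]
  if (anyDuplicated(cn))
    stop("duplicate column label: ", cn[duplicated(cn)][1])
  body <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(body), ncol(body), dimnames = list(rn, cn))
  for (j in seq_len(ncol(body))) {
    cell <- trimws(body[[j]])
    # normalise typographic minus signs to ASCII
    cell <- gsub("−", "-", cell)
    bad <- which(cell == "" | is.na(cell))
    if (length(bad))
      stop(sprintf("empty cell at row '%s', column '%s' in %s",
                   rn[bad[1]], cn[j], path))
    v <- suppressWarnings(as.numeric(cell))
    if (anyNA(v))
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                   cell[which(is.na(v))[1]], rn[which(is.na(v))[1]], cn[j],
                   path))
    m[, j] <- v
  }
  m
}

#' Write a labeled numeric matrix to CSV
#'
#' Inverse of [read_matrix_csv()]: the written file round-trips through the
#' reader with identical labels and values.
#'
#' @param m numeric matrix with dimnames.
#' @param path destination path.
#' @param label_header header of the label column, default `"id"`.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, label_header = "id") {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must have row and column labels")
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- label_header
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expert panel from CSV
#'
#' Expected columns: `expert_id`, `cluster`, `rank`.
#'
#' @param path file path.
#' @return An [expert_panel()].
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "cluster", "rank")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("panel file lacks column(s): ", paste(missing, collapse = ", "))
  expert_panel(df$expert_id, df$cluster, df$rank)
}

#' Read criterion weights from CSV
#'
#' Expected columns: `criterion_id`, `raw_weight`.
#'
#' @param path file path.
#' @return Named numeric vector of raw weights.
#' @export
read_weights_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("criterion_id", "raw_weight")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("weights file lacks column(s): ", paste(missing, collapse = ", "))
  stats::setNames(as.numeric(df$raw_weight), df$criterion_id)
}

#' Read a pipeline configuration file
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`); the parsed list is what
#' [run_pipeline()] accepts. Relative input paths inside the file are
#' resolved against the file's directory.
#'
#' @param path configuration file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yml = ,
                yaml = yaml::read_yaml(path),
                stop("unsupported config extension: .", ext))
  base <- dirname(normalizePath(path))
  for (f in c("panel", "assessments", "weights_tables", "values_tables")) {
    if (is.character(cfg[[f]]))
      cfg[[f]] <- ifelse(file.exists(cfg[[f]]), cfg[[f]],
                         file.path(base, cfg[[f]]))
  }
  cfg
}

#' Load a packaged case-study fixture
#'
#' Two fixtures transcribe the printed tables of the hospital case study
#' (a 20-department accident and trauma hospital), exactly as printed --
#' including the mixed 2-/4-decimal precision of the total-relation matrix
#' and a criterion weight widely suspected to carry a decimal-shift typo;
#' nothing is "corrected". Each bundle's `notes` field records the known
#' transcription caveats.
#'
#' \describe{
#'   \item{`bahonar_table2`}{DEMATEL output: 20 x 20 total-relation matrix
#'     `T` (departments ED20..ED1 in printed order), plus the printed
#'     marginals `R`, `C` and `relation` (R - C) per department.}
#'   \item{`bahonar_table3`}{Weighted-sum matrix: 13 x 20 `weighted_cells`
#'     (12 managerial criteria MR1..MR12 plus the infection-risk row; cells
#'     are already weight-times-value products), the printed normalised
#'     `weights` column, and the printed `ws` totals row.}
#' }
#'
#' @param name fixture name.
#' @return A list of class `"fixture_bundle"` with the tables above plus
#'   `name`, `departments`, `notes`.
#' @export
load_fixture <- function(name) {
  known <- c("bahonar_table2", "bahonar_table3")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  ext <- function(f) system.file("extdata", f, package = "dematelwsm",
                                 mustWork = TRUE)
  if (name == "bahonar_table2") {
    T <- read_matrix_csv(ext("bahonar_table2_T.csv"))
    marg <- utils::read.csv(ext("bahonar_table2_marginals.csv"),
                            stringsAsFactors = FALSE)
    out <- list(name = name,
                T = T,
                R = stats::setNames(marg$R, marg$department),
                C = stats::setNames(marg$C, marg$department),
                relation = stats::setNames(marg$R_minus_C, marg$department),
                departments = marg$department,
                notes = paste("T cells printed at 2 decimals except the",
                              "ED20/ED19/ED18/ED17 columns (4 decimals);",
                              "C printed at 4 decimals for those columns",
                              "only; R and R-C as printed"))
  } else {
    cells <- read_matrix_csv(ext("bahonar_table3_cells.csv"))
    w <- read_weights_csv(ext("bahonar_table3_weights.csv"))
    ws <- utils::read.csv(ext("bahonar_table3_ws.csv"),
                          stringsAsFactors = FALSE)
    out <- list(name = name,
                weighted_cells = cells,
                weights = w,
                ws = stats::setNames(ws$ws, ws$department),
                criteria = rownames(cells),
                departments = colnames(cells),
                notes = paste("cells are already-weighted products W'*V as",
                              "printed; the printed weights column sums to",
                              "~1.368 (suspected decimal-shift typo in MR10),",
                              "stored as printed; ED20 column printed at 2",
                              "decimals, others at 3"))
  }
  structure(out, class = "fixture_bundle")
}

#' Write pipeline artifacts to a run directory
#'
#' Emits the stage outputs of a [run_pipeline()] result as plain files: the
#' consensus and total-relation matrices as CSV, and a JSON report with the
#' per-department DEMATEL scores and classification, risk scores, weighted
#' sums, shortlist and the config snapshot (so a run can be reproduced
#' exactly; no timestamps are embedded).
#'
#' @param x a `"hybrid_ranking"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(unclass(x$dematel$Z), file.path(dir, "consensus_Z.csv"),
                   "department")
  write_matrix_csv(x$dematel$T, file.path(dir, "total_relation_T.csv"),
                   "department")
  cl <- x$dematel$classification
  report <- list(
    departments = x$dematel$departments,
    dematel = list(R = as.list(x$dematel$R),
                   C = as.list(x$dematel$C),
                   prominence = as.list(x$dematel$prominence),
                   relation = as.list(x$dematel$relation),
                   group = stats::setNames(as.list(cl$group), cl$department),
                   master_dispatcher = cl$department[cl$is_master_dispatcher],
                   master_receiver = cl$department[cl$is_master_receiver]),
    risk_scores = as.list(x$risk_scores),
    risk_mode = attr(x$risk_scores, "mapping_mode"),
    ws_totals = as.list(round(x$wsm$totals, 2)),
    ranking = x$wsm$ranking,
    shortlist = x$shortlist$alternative,
    config = x$config[setdiff(names(x$config),
                              c("assessments", "values_tables",
                                "weights_tables", "panel"))]
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
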