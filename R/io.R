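# Delimited-text and JSON interfaces. State files carry one row per frame
# with (subject, condition, frame, state); matrices travel as plain numeric
# CSV grids; solutions, models and reports serialize to JSON with enough
# provenance (seed, parameters) to regenerate them.

#' Read a multi-subject state-sequence file
#'
#' Expects a delimited file with header `subject,condition,frame,state`
#' (frame is used for ordering within each subject x condition block).
#' States must be integers in 1..k; violations are reported with their line
#' number.
#'
#' @param path file path.
#' @param k number of states.
#' @param sep field separator (default comma).
#' @return a [state_sequences()] object.
#' @export
read_state_sequences <- function(path, k, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("subject", "condition", "frame", "state")
  if (!all(need %in% names(df)))
    stop("state file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  st <- suppressWarnings(as.numeric(df$state))
  bad <- which(is.na(st) | st != round(st) | st < 1 | st > k)
  if (length(bad))
    stop("invalid state at line ", bad[1L] + 1L, " of ", path,
         " (value '", df$state[bad[1L]], "', expected integer in 1..", k, ")",
         call. = FALSE)
  ord <- order(df$subject, df$condition, df$frame)
  df <- df[ord, , drop = FALSE]
  state_sequences(df$subject, df$condition, as.integer(df$state), k)
}

#' Write a state-sequence file
#'
#' @param seqs a [state_sequences()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_state_sequences <- function(seqs, path) {
  frame <- stats::ave(seq_len(nrow(seqs)),
                      seqs$subject, seqs$condition, FUN = seq_along)
  utils::write.csv(data.frame(subject = seqs$subject,
                              condition = seqs$condition,
                              frame = frame, state = seqs$state),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a numeric matrix (kernel or joint) from delimited text
#'
#' A k x k numeric grid, optionally with a header row of state labels.
#'
#' @param path file path.
#' @param header whether the first row holds labels.
#' @param sep field separator.
#' @return numeric matrix.
#' @export
read_matrix_csv <- function(path, header = FALSE, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- as.matrix(utils::read.table(path, header = header, sep = sep))
  if (!is.numeric(m)) stop("non-numeric entries in ", path, call. = FALSE)
  dimnames(m) <- NULL
  m
}

#' Read a probability vector (one row of k probabilities)
#'
#' @inheritParams read_matrix_csv
#' @return numeric probability vector (validated).
#' @export
read_probability_vector <- function(path, sep = ",") {
  v <- as.numeric(read_matrix_csv(path, sep = sep))
  check_prob_vector(v, paste0("probability vector in ", path))
  v
}

#' Read an activity matrix with its block manifest
#'
#' The matrix file is a channels x frames numeric grid; the JSON manifest is
#' an array of blocks `{subject, condition, start, n}` (1-based start frame)
#' covering the columns.
#'
#' @param matrix_path delimited-text activity matrix (channels x frames).
#' @param manifest_path JSON manifest.
#' @param sep field separator for the matrix file.
#' @return list of class `activity_data` with `x`, `subject`, `condition`.
#' @export
read_activity <- function(matrix_path, manifest_path, sep = ",") {
  x <- read_matrix_csv(matrix_path, sep = sep)
  man <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = TRUE)
  need <- c("subject", "condition", "start", "n")
  if (!all(need %in% names(man)))
    stop("manifest must provide fields ", paste(need, collapse = ", "),
         call. = FALSE)
  subject <- condition <- rep(NA_character_, ncol(x))
  for (r in seq_len(nrow(man))) {
    idx <- man$start[r] + seq_len(man$n[r]) - 1L
    if (any(idx < 1L) || any(idx > ncol(x)))
      stop("manifest block ", r, " exceeds the matrix frame range",
           call. = FALSE)
    subject[idx] <- man$subject[r]
    condition[idx] <- man$condition[r]
  }
  if (anyNA(subject))
    stop("manifest does not cover every frame of the matrix", call. = FALSE)
  structure(list(x = x, subject = subject, condition = condition),
            class = "activity_data")
}

#' Serialize a bridge solution to JSON
#'
#' @param solution a [solve_bridge()] result.
#' @param path output file; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_bridge_solution <- function(solution, path = NULL) {
  stopifnot(inherits(solution, "bridge_solution"))
  obj <- list(states = length(solution$pi),
              pi = solution$pi, pi_target = solution$pi_target,
              T = solution$horizon, cost_nats = solution$cost,
              alpha = solution$alpha, beta = solution$beta,
              optimal_joint = solution$optimal_joint,
              iterations = solution$iterations,
              residual = solution$residual,
              converged = solution$converged, tol = solution$tol)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write a cost table (and optional asymmetry matrix) to CSV + JSON
#'
#' @param table a [pairwise_costs()] result.
#' @param prefix output path prefix; writes `<prefix>_mean.csv`,
#'   `<prefix>_sd.csv` and `<prefix>.json`.
#' @return the JSON path, invisibly.
#' @export
write_cost_table <- function(table, prefix) {
  stopifnot(inherits(table, "cost_table"))
  utils::write.csv(table$mean, paste0(prefix, "_mean.csv"))
  utils::write.csv(table$sd, paste0(prefix, "_sd.csv"))
  obj <- list(conditions = table$conditions, mean = table$mean,
              sd = table$sd, n_replicates = table$n_replicates,
              baseline = table$baseline, T = table$T, seed = table$seed,
              n_infeasible = table$n_infeasible, notes = table$notes)
  path <- paste0(prefix, ".json")
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              matrix = "rowmajor"), path)
  invisible(path)
}

#' Read or write a run configuration (YAML or JSON by extension)
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- list(k = 8L, T = 1L, n_replicates = 100L, tol = 1e-10,
                   max_iter = 1e5, baseline = "rest", seed = 1L)
  out <- utils::modifyList(defaults, cfg)
  if (out$k < 2 || out$T < 1 || out$n_replicates < 2)
    stop("invalid configuration: need k >= 2, T >= 1, n_replicates >= 2",
         call. = FALSE)
  out
}

#' @rdname read_run_config
#' @param config named list to write.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(config, path) else
    writeLines(jsonlite::toJSON(config, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}
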