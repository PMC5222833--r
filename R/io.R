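# Result serialization: plain delimited tables with a structured-text
# metadata sidecar (DCF), so every output file is self-describing and
# round-trips losslessly.

RESULT_COLUMNS <- c("N", "P", "alpha", "reps", "seed",
                    "p_B_hat", "ci_bit", "p_V_hat", "ci_vec", "N_V_hat",
                    "p_B_theory", "p_V_theory", "N_V_theory",
                    "retain_diagonal")

#' @export
as.data.frame.retrieval_estimate <- function(x, ...) {
  data.frame(N = x$N, P = x$P, alpha = x$P / x$N, reps = x$reps,
             seed = x$seed,
             p_B_hat = x$p_B_hat, ci_bit = x$ci_halfwidth_bit,
             p_V_hat = x$p_V_hat, ci_vec = x$ci_halfwidth_vector,
             N_V_hat = x$N_V_hat,
             p_B_theory = p_bit_error(x$N, x$P, x$retain_diagonal),
             p_V_theory = p_vector_error(x$N, x$P, x$retain_diagonal),
             N_V_theory = expected_unrecovered(x$N, x$P, x$retain_diagonal),
             retain_diagonal = x$retain_diagonal)
}

#' @export
as.data.frame.spurious_estimate <- function(x, ...) {
  data.frame(N = x$N, P = x$P, alpha = x$P / x$N, reps = x$reps,
             probes = x$probes, seed = x$seed,
             pbar_B_hat = x$pbar_B_hat, ci_bit = x$ci_halfwidth_bit,
             pbar_V_hat = x$pbar_V_hat, ci_vec = x$ci_halfwidth_vector,
             pbar_B_theory = spurious_error_prob(x$N, x$P, "bit"),
             pbar_V_theory = spurious_error_prob(x$N, x$P, "vector"))
}

#' Write results as a delimited table with a metadata sidecar
#'
#' Writes a tab-delimited table with a fixed, documented column order (the
#' standard retrieval columns first, in a stable order across runs; columns
#' absent from the records are emitted as empty fields, never dropped) plus
#' a `<path>.meta` sidecar in DCF ("Debian Control File" key: value) format
#' recording the package version, timestamp and full parameter echo — enough
#' to regenerate the table.
#'
#' @param records A data frame (e.g. a `capacity_grid`) or an estimate
#'   object with an `as.data.frame` method.
#' @param path Output file path.
#' @param format `"delimited_table"` (table plus sidecar) or
#'   `"structured_metadata"` (sidecar only).
#' @param metadata Named list of run parameters to record in the sidecar.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(records, path,
                          format = c("delimited_table",
                                     "structured_metadata"),
                          metadata = list()) {
  format <- match.arg(format)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("output directory does not exist: ", dirname(path),
                    call. = FALSE)
  df <- as.data.frame(records)
  missing_cols <- setdiff(RESULT_COLUMNS, names(df))
  for (cn in missing_cols) df[[cn]] <- NA
  df <- df[, c(RESULT_COLUMNS, setdiff(names(df), RESULT_COLUMNS)),
           drop = FALSE]

  meta <- c(list(package = "hopcapacity",
                 version = as.character(utils::packageVersion("hopcapacity")),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 n_records = nrow(df)),
            metadata)
  meta <- lapply(meta, function(v) paste(format(v, trim = TRUE),
                                         collapse = ", "))

  if (format == "delimited_table") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write.dcf(as.data.frame(meta, stringsAsFactors = FALSE),
            file = paste0(path, ".meta"))
  invisible(path)
}

#' Read back a results table and its metadata sidecar
#'
#' @param path Path given to [write_results()].
#' @return A list with `records` (data frame) and `metadata` (named list;
#'   `NULL` when no sidecar is present).
#' @export
read_results <- function(path) {
  records <- utils::read.table(path, sep = "\t", header = TRUE)
  meta_path <- paste0(path, ".meta")
  metadata <- NULL
  if (file.exists(meta_path)) {
    m <- read.dcf(meta_path)
    metadata <- as.list(m[1, ])
  }
  list(records = records, metadata = metadata)
}
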