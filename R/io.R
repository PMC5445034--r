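#' Read and write tool rankings as delimited text
#'
#' Long-format tab-separated text with columns `tool_name`, `challenge_id`,
#' `rank` and either `key_block` or `inchikey` (the first block is
#' extracted).  Ranks must be 1-based and contiguous within each
#' (tool, challenge) pair.
#'
#' @param path file path.
#' @return `read_tool_rankings()`: named list tool -> named list
#'   challenge_id -> character vector of key blocks, the structure every
#'   consensus/evaluation function consumes.
#' @export
read_tool_rankings <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "")
  for (col in c("tool_name", "challenge_id", "rank")) {
    if (!col %in% names(df)) config_error("rankings file lacks column '", col, "'")
  }
  if (!"key_block" %in% names(df)) {
    if (!"inchikey" %in% names(df)) {
      config_error("rankings file needs a 'key_block' or 'inchikey' column")
    }
    df$key_block <- first_block(df$inchikey)
  }
  out <- lapply(split(df, df$tool_name), function(tdf) {
    lapply(split(tdf, tdf$challenge_id), function(cdf) {
      r <- cdf$key_block[order(cdf$rank)]
      if (length(r) == 0L || any(sort(cdf$rank) != seq_along(r)) ||
          anyDuplicated(r)) {
        stop("non-contiguous or duplicated ranks for tool ",
             sQuote(cdf$tool_name[1]), ", challenge ",
             sQuote(cdf$challenge_id[1]), call. = FALSE)
      }
      r
    })
  })
  out
}

#' @param rankings_by_tool named list tool -> named list challenge_id ->
#'   ranking, as produced by [simulate_tools()] or [read_tool_rankings()].
#' @rdname read_tool_rankings
#' @export
write_tool_rankings <- function(rankings_by_tool, path) {
  rows <- do.call(rbind, lapply(names(rankings_by_tool), function(tool) {
    do.call(rbind, lapply(names(rankings_by_tool[[tool]]), function(cid) {
      r <- rankings_by_tool[[tool]][[cid]]
      data.frame(tool_name = tool, challenge_id = cid,
                 rank = seq_along(r), key_block = r,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write calibrated sensitivity weights
#'
#' Flat tab-separated key-value text (`tool_name`, `k`, `omega`) so a
#' validation run can reuse the calibration computed on a training set.
#'
#' @param path file path.
#' @param k_use which k the consensus should divide by (stored on read as
#'   the `k_use` attribute).
#' @return `read_weights()`: a `"sensitivity_weights"` data.frame.
#' @export
read_weights <- function(path, k_use = 10) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in c("tool_name", "k", "omega")) {
    if (!col %in% names(df)) config_error("weights file lacks column '", col, "'")
  }
  structure(df[, c("tool_name", "k", "omega")],
            class = c("sensitivity_weights", "data.frame"),
            k_use = k_use,
            calibrated_on = list(label = path, n = NA_integer_))
}

#' @param weights a [calibrate()] result.
#' @rdname read_weights
#' @export
write_weights <- function(weights, path) {
  utils::write.table(as.data.frame(weights)[, c("tool_name", "k", "omega")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a database-membership table
#'
#' Long-format tab-separated text with columns `key_block` and
#' `database_name`, one row per membership.
#'
#' @param path file path.
#' @param vocabulary optional allowed database names (see [db_table()]).
#' @return `read_db_table()`: a [db_table()].
#' @export
read_db_table <- function(path, vocabulary = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  db_table(df, vocabulary = vocabulary)
}

#' @param table a [db_table()].
#' @rdname read_db_table
#' @export
write_db_table <- function(table, path) {
  stopifnot(inherits(table, "db_table"))
  rows <- do.call(rbind, lapply(names(table$sets), function(kb) {
    data.frame(key_block = kb, database_name = table$sets[[kb]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(key_block = character(0), database_name = character(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read challenge truths from delimited text
#'
#' Tab-separated text with columns `challenge_id` and `key_block` (or
#' `inchikey`, from which the first block is extracted).
#'
#' @param path file path.
#' @return named character vector challenge_id -> truth key block.
#' @export
read_truths <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!"challenge_id" %in% names(df)) {
    config_error("truths file lacks column 'challenge_id'")
  }
  kb <- if ("key_block" %in% names(df)) df$key_block
        else if ("inchikey" %in% names(df)) first_block(df$inchikey)
        else config_error("truths file needs a 'key_block' or 'inchikey' column")
  stats::setNames(kb, df$challenge_id)
}

#' Write a synthetic dataset to disk in the package's exchange formats
#'
#' Materializes a [generate_dataset()] result as the delimited files the
#' other readers consume: one candidate CSV per challenge under
#' `candidates/`, `rankings.tsv`, `truths.tsv`, `db_table.tsv`, and --
#' when the dataset carries spectra -- `queries.mgf` and `library.msp`.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "candidates"), recursive = TRUE, showWarnings = FALSE)
  for (cid in names(dataset$challenges)) {
    utils::write.csv(dataset$challenges[[cid]]$candidates,
                     file.path(dir, "candidates", paste0(cid, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  write_tool_rankings(dataset$rankings_by_tool, file.path(dir, "rankings.tsv"))
  utils::write.table(
    data.frame(challenge_id = names(dataset$truths),
               key_block = unname(dataset$truths)),
    file.path(dir, "truths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_db_table(dataset$db_table, file.path(dir, "db_table.tsv"))
  if (!is.null(dataset$queries)) {
    write_mgf(unname(dataset$queries), file.path(dir, "queries.mgf"))
    write_msp(dataset$library, file.path(dir, "library.msp"))
  }
  invisible(dir)
}
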