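#' Default column mapping for CIS-BP-style TF annotation tables
#'
#' Follows the TF_Information.txt convention. Supply a modified copy to
#' [read_tf_table()] to tolerate dialect drift between database versions.
#'
#' @return Named character vector mapping logical fields to column names.
#' @export
cisbp_columns <- function() {
  c(tf_id = "TF_ID", tf_name = "TF_Name", species = "TF_Species",
    dbd_class = "Family_Name", motif_id = "Motif_ID",
    motif_type = "Motif_Type", status = "TF_Status")
}

#' Read a CIS-BP-style TF annotation table
#'
#' Parses a tab-separated table with one row per TF-motif association and
#' aggregates it into one record per distinct TF. The CIS-BP null motif
#' token `"."` yields a TF with an empty PWM set (retained, but excluded
#' from family analysis by default downstream). Ingest counts — TFs with
#' and without motifs, and distinct PWM IDs — are reported via `message()`
#' so either inclusion convention can be reproduced.
#'
#' @param path path to the TSV file.
#' @param species_filter optional species name; keep matching rows only.
#' @param columns column mapping, see [cisbp_columns()].
#' @param quiet suppress the ingest-count message.
#' @return A `tf_dataset`: list of TF records, each a list with `tf_id`,
#'   `tf_name`, `species`, `dbd_class`, `pwm_ids` (character, possibly
#'   empty) and `provenance` (named "direct"/"inferred" per pwm id, from
#'   the motif-type column: CIS-BP marks direct evidence with type "D").
#' @export
read_tf_table <- function(path, species_filter = NULL,
                          columns = cisbp_columns(), quiet = FALSE) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("malformed TF table: missing required column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("empty TF table", call. = FALSE)
    return(structure(list(), class = "tf_dataset"))
  }
  if (!is.null(species_filter)) {
    raw <- raw[raw[[columns[["species"]]]] == species_filter, , drop = FALSE]
  }
  ids <- unique(raw[[columns[["tf_id"]]]])
  records <- lapply(ids, function(id) {
    rows <- raw[raw[[columns[["tf_id"]]]] == id, , drop = FALSE]
    motifs <- rows[[columns[["motif_id"]]]]
    keep <- !(motifs %in% c(".", "", NA))
    pwm_ids <- unique(motifs[keep])
    prov <- character(0)
    if (length(pwm_ids) > 0L) {
      types <- rows[[columns[["motif_type"]]]][keep]
      prov <- vapply(pwm_ids, function(m) {
        if (any(types[motifs[keep] == m] %in% c("D", "direct"))) "direct"
        else "inferred"
      }, character(1))
    }
    list(tf_id = id,
         tf_name = rows[[columns[["tf_name"]]]][1],
         species = rows[[columns[["species"]]]][1],
         dbd_class = rows[[columns[["dbd_class"]]]][1],
         pwm_ids = pwm_ids,
         provenance = prov)
  })
  ds <- structure(records, class = "tf_dataset")
  if (!quiet) {
    n_with <- sum(vapply(records, function(r) length(r$pwm_ids) > 0,
                         logical(1)))
    message(sprintf(
      "read %d TFs (%d with >=1 PWM, %d without), %d distinct PWM IDs",
      length(records), n_with, length(records) - n_with,
      length(unique(unlist(lapply(records, `[[`, "pwm_ids"))))))
  }
  ds
}

#' @export
print.tf_dataset <- function(x, ...) {
  n_with <- sum(vapply(x, function(r) length(r$pwm_ids) > 0, logical(1)))
  cat(sprintf("TF dataset: %d TFs (%d with PWMs), %d distinct PWM IDs\n",
              length(x), n_with,
              length(unique(unlist(lapply(x, `[[`, "pwm_ids"))))))
  invisible(x)
}

#' Flatten a TF dataset to an association table
#'
#' @param records a `tf_dataset`.
#' @return Data frame with one row per TF-PWM association (TFs without PWMs
#'   contribute one row with `motif_id = NA`).
#' @export
tf_associations <- function(records) {
  stopifnot(inherits(records, "tf_dataset"))
  do.call(rbind, lapply(records, function(r) {
    motifs <- if (length(r$pwm_ids) > 0) r$pwm_ids else NA_character_
    prov <- if (length(r$pwm_ids) > 0) unname(r$provenance) else NA_character_
    data.frame(tf_id = r$tf_id, tf_name = r$tf_name, species = r$species,
               dbd_class = r$dbd_class, motif_id = motifs,
               provenance = prov, row.names = NULL)
  }))
}

#' Read a CIS-BP-format PWM file
#'
#' Expects a header line `Pos A C G T` followed by one numbered row per
#' motif position with the four base probabilities (alphabet order fixed to
#' A, C, G, T). Rows are renormalized to sum exactly to 1 when within
#' `tol` of 1, and rejected otherwise.
#'
#' @param path path to the PWM text file.
#' @param motif_id motif identifier; default the file name without
#'   extension.
#' @param tol acceptance tolerance on raw row sums (default 1e-3, generous
#'   enough for matrices printed with few decimals).
#' @return A `pwm_matrix`: list with `motif_id`, `probs` (L x 4 matrix,
#'   columns A,C,G,T, rows summing to 1 within 1e-6) and `L`.
#' @export
read_pwm <- function(path, motif_id = NULL, tol = 1e-3) {
  if (is.null(motif_id)) {
    motif_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.delim(path, check.names = FALSE)
  need <- c("Pos", "A", "C", "G", "T")
  if (!all(need %in% names(raw))) {
    stop(sprintf("malformed PWM file %s: header must name %s",
                 path, paste(need, collapse = " ")), call. = FALSE)
  }
  m <- as.matrix(raw[, c("A", "C", "G", "T")])
  if (!is.numeric(m) || anyNA(m)) {
    stop(sprintf("malformed PWM file %s: non-numeric probability cell",
                 path), call. = FALSE)
  }
  pwm_matrix(motif_id, m, tol = tol)
}

#' Construct and validate a PWM
#'
#' @param motif_id motif identifier string.
#' @param probs L x 4 numeric matrix of base probabilities, columns in
#'   A, C, G, T order.
#' @param tol acceptance tolerance on row sums before renormalization.
#' @return A validated `pwm_matrix` object.
#' @export
pwm_matrix <- function(motif_id, probs, tol = 1e-6) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L || nrow(probs) < 1L) {
    stop("PWM must be an L x 4 matrix with L >= 1", call. = FALSE)
  }
  if (any(probs < 0 | probs > 1)) {
    stop("PWM entries must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > tol)) {
    stop(sprintf(
      "invalid PWM %s: row %d sums to %.4f (tolerance %g)",
      motif_id, which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))], tol),
      call. = FALSE)
  }
  probs <- probs / rs
  colnames(probs) <- c("A", "C", "G", "T")
  rownames(probs) <- NULL
  structure(list(motif_id = motif_id, probs = probs, L = nrow(probs)),
            class = "pwm_matrix")
}

#' @export
print.pwm_matrix <- function(x, ...) {
  cons <- paste(c("A", "C", "G", "T")[apply(x$probs, 1, which.max)],
                collapse = "")
  cat(sprintf("PWM %s: %d positions, consensus %s\n", x$motif_id, x$L, cons))
  invisible(x)
}

#' Write a dataset in the CIS-BP dialect
#'
#' Emits one annotation table (`TF_Information.txt`) and one PWM file per
#' matrix under `pwms/`, re-readable by [read_tf_table()] and [read_pwm()].
#' Rows are sorted and numbers formatted with fixed precision so identical
#' datasets produce byte-identical files.
#'
#' @param records a `tf_dataset` (or plain list of TF records).
#' @param pwms list of `pwm_matrix` objects; every motif id referenced by a
#'   record must have a matrix here or be listed in `id_only`.
#' @param out_dir output directory (created if needed).
#' @param id_only character vector of motif ids intentionally written
#'   without a matrix file.
#' @return Invisibly, the paths written (table first).
#' @export
write_cisbp_like <- function(records, pwms = list(), out_dir,
                             id_only = character(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory %s", out_dir),
         call. = FALSE)
  }
  pwm_ids <- vapply(pwms, `[[`, character(1), "motif_id")
  referenced <- unique(unlist(lapply(records, `[[`, "pwm_ids")))
  orphan <- setdiff(referenced, c(pwm_ids, id_only))
  if (length(orphan) > 0L) {
    stop(sprintf("motif id(s) %s referenced but have no matrix ",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  cols <- cisbp_columns()
  rows <- lapply(records, function(r) {
    motifs <- if (length(r$pwm_ids) > 0) sort(r$pwm_ids) else "."
    types <- if (length(r$pwm_ids) > 0) {
      ifelse(unname(r$provenance[motifs]) == "direct", "D", "I")
    } else "."
    data.frame(r$tf_id, r$tf_name, r$species, r$dbd_class, motifs, types,
               "reviewed", stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(matrix(character(0), ncol = 7))
  }
  names(tab) <- unname(cols[c("tf_id", "tf_name", "species", "dbd_class",
                              "motif_id", "motif_type", "status")])
  tab <- tab[order(tab[[1]], tab[[5]]), , drop = FALSE]
  table_path <- file.path(out_dir, "TF_Information.txt")
  utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pwm_dir <- file.path(out_dir, "pwms")
  if (length(pwms) > 0L) dir.create(pwm_dir, showWarnings = FALSE)
  pwm_paths <- character(0)
  for (p in pwms[order(pwm_ids)]) {
    df <- data.frame(Pos = seq_len(p$L),
                     A = sprintf("%.6f", p$probs[, "A"]),
                     C = sprintf("%.6f", p$probs[, "C"]),
                     G = sprintf("%.6f", p$probs[, "G"]),
                     T = sprintf("%.6f", p$probs[, "T"]))
    fp <- file.path(pwm_dir, paste0(p$motif_id, ".txt"))
    utils::write.table(df, fp, sep = "\t", quote = FALSE, row.names = FALSE)
    pwm_paths <- c(pwm_paths, fp)
  }
  invisible(c(table_path, pwm_paths))
}

#' Read back a directory written by [write_cisbp_like()]
#'
#' @param dir dataset directory.
#' @param ... passed to [read_tf_table()].
#' @return List with `records` (a `tf_dataset`) and `pwms` (named list of
#'   `pwm_matrix`).
#' @export
read_cisbp_dir <- function(dir, ...) {
  records <- read_tf_table(file.path(dir, "TF_Information.txt"), ...)
  pwm_files <- sort(list.files(file.path(dir, "pwms"), pattern = "\\.txt$",
                               full.names = TRUE))
  pwms <- lapply(pwm_files, read_pwm)
  names(pwms) <- vapply(pwms, `[[`, character(1), "motif_id")
  list(records = records, pwms = pwms)
}
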