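# Data model and readers/writers for replicate-level Cq tables, sample
# sheets and assay panels. The canonical on-disk format is long (tidy) CSV;
# wide sample-by-assay matrices are an import convenience only. Undetected
# reactions are a distinct state (NA in memory, "Undetermined" on disk),
# never encoded as Cq 40.

.CQ_SCHEMA_VERSION <- "1"
.UNDETECTED_TOKENS <- c("undetermined", "undetected", "na", "n/a", "")

#' Construct a replicate-level Cq dataset
#'
#' Bundles replicate-level quantification-cycle (Cq) measurements with a
#' sample sheet (sample-to-group assignment) and an assay panel (role and
#' optional amplification efficiency per assay), and validates the
#' cross-references between them.
#'
#' @param measurements data.frame with columns `sample_id`, `assay_id`,
#'   `replicate`, `plate_id`, `cq`. `cq` is numeric; `NA` marks an
#'   undetected (instrument "Undetermined") reaction.
#' @param samples sample sheet: data.frame with `sample_id`, `group` and
#'   optional extra columns (e.g. `patient_id`).
#' @param panel assay panel: data.frame with `assay_id`, `rna_class`
#'   (one of miRNA, snoRNA, other), `role` (one of reference_candidate,
#'   target, control) and optional `efficiency` (percent, in (50, 150)).
#' @return An object of class `cq_dataset`.
#' @export
cq_dataset <- function(measurements, samples, panel) {
  x <- structure(
    list(measurements = as.data.frame(measurements),
         samples = as.data.frame(samples),
         panel = as.data.frame(panel)),
    class = "cq_dataset")
  validate_cq_dataset(x)
}

#' Validate a Cq dataset
#'
#' Checks column presence, uniqueness of identifiers and of
#' (sample, assay, replicate) measurement keys, that every measurement
#' refers to a known sample and assay, and value-range invariants
#' (positive finite Cq, efficiency within (50, 150)).
#'
#' @param x a `cq_dataset`.
#' @return `x`, invisibly-validated (returned unchanged).
#' @export
validate_cq_dataset <- function(x) {
  stopifnot(inherits(x, "cq_dataset"))
  m <- x$measurements; s <- x$samples; p <- x$panel

  need <- c("sample_id", "assay_id", "replicate", "plate_id", "cq")
  missing_cols <- setdiff(need, names(m))
  .check(length(missing_cols) == 0, "measurements",
         paste("missing columns:", paste(missing_cols, collapse = ", ")))
  .check(all(c("sample_id", "group") %in% names(s)), "samples",
         "must have columns sample_id, group")
  .check(all(c("assay_id", "role") %in% names(p)), "panel",
         "must have columns assay_id, role")

  .check(!anyDuplicated(s$sample_id), "samples", "duplicate sample_id")
  .check(!anyDuplicated(p$assay_id), "panel", "duplicate assay_id")

  unknown_s <- setdiff(unique(m$sample_id), s$sample_id)
  .check(length(unknown_s) == 0, "measurements",
         paste("sample_id not in sample sheet:",
               paste(unknown_s, collapse = ", ")))
  unknown_a <- setdiff(unique(m$assay_id), p$assay_id)
  .check(length(unknown_a) == 0, "measurements",
         paste("assay_id not in panel:", paste(unknown_a, collapse = ", ")))

  key <- paste(m$sample_id, m$assay_id, m$replicate, sep = "\r")
  dup <- key[duplicated(key)]
  .check(length(dup) == 0, "measurements",
         paste("duplicate (sample, assay, replicate) keys:",
               paste(utils::head(gsub("\r", "/", dup), 5), collapse = "; ")))

  .check(is.numeric(m$cq), "measurements", "cq must be numeric (NA = undetected)")
  bad_cq <- which(!is.na(m$cq) & (!is.finite(m$cq) | m$cq <= 0))
  .check(length(bad_cq) == 0, "measurements",
         paste("non-positive or non-finite cq at rows:",
               paste(utils::head(bad_cq, 5), collapse = ", ")))
  .check(all(m$replicate >= 1), "measurements", "replicate index must be >= 1")

  if ("efficiency" %in% names(p)) {
    eff <- p$efficiency[!is.na(p$efficiency)]
    .check(all(eff > 50 & eff < 150), "panel",
           "efficiency (percent) must lie in (50, 150)")
  }
  x
}

#' @export
print.cq_dataset <- function(x, ...) {
  cat(sprintf(
    "<cq_dataset> %d measurements | %d samples (%s) | %d assays\n",
    nrow(x$measurements), nrow(x$samples),
    paste(sprintf("%s: %d", names(table(x$samples$group)),
                  as.integer(table(x$samples$group))), collapse = ", "),
    nrow(x$panel)))
  n_und <- sum(is.na(x$measurements$cq))
  cat(sprintf("  undetected: %d (%.1f%%)\n", n_und,
              100 * n_und / max(1, nrow(x$measurements))))
  invisible(x)
}

.parse_cq <- function(x) {
  x_chr <- trimws(as.character(x))
  out <- rep(NA_real_, length(x_chr))
  und <- is.na(x_chr) | tolower(x_chr) %in% .UNDETECTED_TOKENS
  val <- suppressWarnings(as.numeric(x_chr[!und]))
  if (anyNA(val)) {
    bad <- which(!und)[is.na(val)]
    stop(sprintf("unparseable Cq value(s) at row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  out[!und] <- val
  out
}

#' Load a Cq dataset from CSV files
#'
#' Reads a Cq table (long or wide), a sample sheet and an assay panel, and
#' returns a validated [cq_dataset()]. In the long dialect the Cq table has
#' columns `sample_id, assay_id, replicate, plate_id, cq`; cells reading
#' "Undetermined", "Undetected" or empty map to the undetected marker. A
#' wide table (first column `sample_id`, one column per assay) is melted to
#' replicate-level records with replicate index 1 and plate `"plate1"`.
#'
#' @param cq_path path to the Cq CSV.
#' @param samples_path path to the sample sheet CSV (`sample_id, group, ...`).
#' @param panel_path path to the assay panel CSV (`assay_id, role, ...`).
#' @param format `"long"` (default) or `"wide"`.
#' @param sep field separator (`","` or `"\t"`).
#' @return A validated `cq_dataset`.
#' @export
load_dataset <- function(cq_path, samples_path, panel_path,
                         format = c("long", "wide"), sep = ",") {
  format <- match.arg(format)
  for (p in c(cq_path, samples_path, panel_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  read1 <- function(path) {
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  raw <- read1(cq_path)
  if (format == "long") {
    need <- c("sample_id", "assay_id", "replicate", "cq")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols))
      stop(sprintf("Cq table missing columns: %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    if (!"plate_id" %in% names(raw)) raw$plate_id <- "plate1"
    m <- data.frame(sample_id = as.character(raw$sample_id),
                    assay_id = as.character(raw$assay_id),
                    replicate = as.integer(raw$replicate),
                    plate_id = as.character(raw$plate_id),
                    cq = .parse_cq(raw$cq),
                    stringsAsFactors = FALSE)
  } else {
    if (names(raw)[1] != "sample_id")
      stop("wide Cq table must have 'sample_id' as its first column",
           call. = FALSE)
    assays <- names(raw)[-1]
    m <- do.call(rbind, lapply(assays, function(a) {
      data.frame(sample_id = as.character(raw$sample_id), assay_id = a,
                 replicate = 1L, plate_id = "plate1",
                 cq = .parse_cq(raw[[a]]), stringsAsFactors = FALSE)
    }))
  }
  samples <- read1(samples_path)
  panel <- read1(panel_path)
  if ("efficiency" %in% names(panel))
    panel$efficiency <- suppressWarnings(as.numeric(panel$efficiency))
  cq_dataset(m, samples, panel)
}

#' Save a Cq dataset to canonical long-format CSV
#'
#' Writes three files: the Cq table (undetected cells written as
#' `"Undetermined"`, fixed column order, header comment with the schema
#' version), the sample sheet and the assay panel. Re-reading with
#' [load_dataset()] reproduces the dataset exactly.
#'
#' @param dataset a validated `cq_dataset`.
#' @param cq_path,samples_path,panel_path output paths.
#' @return `cq_path`, invisibly.
#' @export
save_dataset <- function(dataset, cq_path,
                         samples_path = sub("\\.csv$", "_samples.csv", cq_path),
                         panel_path = sub("\\.csv$", "_panel.csv", cq_path)) {
  validate_cq_dataset(dataset)
  m <- dataset$measurements[, c("sample_id", "assay_id", "replicate",
                                "plate_id", "cq")]
  m$cq <- ifelse(is.na(m$cq), "Undetermined", format(m$cq, digits = 15))
  con <- file(cq_path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cq_dataset schema v%s", .CQ_SCHEMA_VERSION), con)
  utils::write.table(m, con, sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$samples, samples_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(dataset$panel, panel_path, row.names = FALSE, quote = FALSE)
  invisible(cq_path)
}
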