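#' Canonical columns of a branch measurement table
#'
#' A branch table holds one row per sampled branch: functional (stained)
#' conduit counts at the basal and apical cross-sections, mean lumen
#' diameters at both sections, and the path distance from the shoot apex to
#' each section. All lengths are in centimeters and diameters in
#' micrometers; every downstream fit and furcation predictor assumes these
#' units.
#'
#' @format Character vector of canonical column names.
#' @export
branch_cols <- c(
  "species_id", "n_base", "n_tip",
  "d_base_um", "d_tip_um",
  "dist_base_cm", "dist_tip_cm",
  "branched"
)

#' Coerce a data frame to a canonical branch table
#'
#' Checks that the canonical measurement columns are present, coerces them
#' to the expected types, adds `branched = FALSE` where absent, and computes
#' nothing else: validation is a separate, non-mutating step
#' ([validate_branches()]).
#'
#' @param data A data frame with at least the columns in [branch_cols]
#'   (except `branched`, which is optional).
#' @param provenance Free-text source tag stored as an attribute.
#' @return A tibble with the canonical columns, `provenance` attribute set.
#' @export
as_branch_table <- function(data, provenance = "user") {
  stopifnot(is.data.frame(data))
  need <- setdiff(branch_cols, c("branched", names(data)))
  if (length(need) > 0) {
    stop("missing mandatory column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  if (!"branched" %in% names(out)) out$branched <- FALSE
  out <- dplyr::mutate(
    out,
    species_id = as.character(.data$species_id),
    dplyr::across(c("n_base", "n_tip"), as.numeric),
    dplyr::across(c("d_base_um", "d_tip_um", "dist_base_cm", "dist_tip_cm"),
                  as.numeric),
    branched = as.logical(.data$branched)
  )
  out <- dplyr::relocate(out, dplyr::all_of(branch_cols))
  attr(out, "provenance") <- provenance
  out
}

#' Read a branch measurement table from CSV
#'
#' Reads a delimited text file of per-branch measurements into the canonical
#' branch table. Column names in the file are mapped onto the canonical
#' fields through `column_map`, so the loader never hard-codes a particular
#' header convention. Rows that fail numeric coercion or violate record
#' invariants are flagged in the attached validation report (and a warning
#' summarises them), but all rows are returned: dropping data is left to the
#' caller.
#'
#' Two relaxations cover common file layouts:
#' * If the file records only a total branch length (map it to
#'   `total_length`), `dist_base_cm` is set to that length and
#'   `dist_tip_cm` to `tip_offset_cm`, with a prominent warning.
#' * If apical conduit counts are split across daughter twigs (map the
#'   columns to `n_tip_daughters`), they are summed into `n_tip` and the
#'   row is flagged `branched = TRUE`.
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map Named character vector mapping canonical field names
#'   (names) to file column names (values), e.g.
#'   `c(species_id = "Species", n_base = "NBase", ...)`. Canonical names
#'   already present in the file need not be mapped. The special entry
#'   `n_tip_daughters` may be a vector of several file columns.
#' @param length_unit Unit of the distance columns in the file; `"m"` is
#'   converted to centimeters.
#' @param diameter_unit Unit of the diameter columns; `"mm"` is converted
#'   to micrometers.
#' @param tip_offset_cm Leafy-tip offset used when only a total branch
#'   length is available (default 10 cm).
#' @return A branch table (tibble). The validation report is attached as
#'   attribute `"validation"`.
#' @seealso [validate_branches()], [write_branch_table()]
#' @export
read_branch_table <- function(path, column_map = NULL,
                              length_unit = c("cm", "m"),
                              diameter_unit = c("um", "mm"),
                              tip_offset_cm = 10) {
  length_unit <- match.arg(length_unit)
  diameter_unit <- match.arg(diameter_unit)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols())

  daughters <- NULL
  if (!is.null(column_map)) {
    daughters <- column_map[names(column_map) == "n_tip_daughters"]
    column_map <- column_map[names(column_map) != "n_tip_daughters"]
    missing_src <- setdiff(unname(c(column_map, daughters)), names(raw))
    if (length(missing_src) > 0) {
      stop("column_map refers to absent column(s): ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    raw <- dplyr::rename(raw, !!!rlang::set_names(column_map,
                                                  names(column_map)))
  }

  if (length(daughters) > 0) {
    dcols <- unname(daughters)
    raw$n_tip <- rowSums(as.matrix(raw[dcols]), na.rm = TRUE)
    raw$branched <- TRUE
  }

  if (!"dist_base_cm" %in% names(raw) && "total_length" %in% names(raw)) {
    warning("file provides only total branch length; using it as ",
            "dist_base_cm and a ", tip_offset_cm,
            " cm leafy-tip offset as dist_tip_cm", call. = FALSE)
    raw$dist_base_cm <- as.numeric(raw$total_length)
    raw$dist_tip_cm <- tip_offset_cm
  }

  need <- setdiff(branch_cols, c("branched", names(raw)))
  if (length(need) > 0) {
    stop("missing mandatory column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }

  if (length_unit == "m") {
    raw$dist_base_cm <- raw$dist_base_cm * 100
    raw$dist_tip_cm <- raw$dist_tip_cm * 100
  }
  if (diameter_unit == "mm") {
    raw$d_base_um <- raw$d_base_um * 1000
    raw$d_tip_um <- raw$d_tip_um * 1000
  }

  out <- suppressWarnings(as_branch_table(raw, provenance = path))
  report <- validate_branches(out)
  if (nrow(report) > 0) {
    warning(sum(report$severity == "error"), " error(s) and ",
            sum(report$severity == "warning"),
            " warning(s) in branch table; see attr(x, \"validation\")",
            call. = FALSE)
  }
  attr(out, "validation") <- report
  out
}

#' Write a branch table to CSV
#'
#' Canonical headers, full double precision; reading the file back with
#' [read_branch_table()] reproduces every field exactly.
#'
#' @param data A branch table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_branch_table <- function(data, path) {
  data <- as_branch_table(data, provenance = attr(data, "provenance") %||% "user")
  readr::write_csv(data[branch_cols], path)
  invisible(path)
}

#' Validate a branch table
#'
#' Applies the record-level invariants and returns a structured report,
#' never mutating the data. Errors: conduit counts below 1 or non-finite,
#' non-positive diameters or distances, apex distances out of order
#' (`dist_base_cm <= dist_tip_cm` means the segment has no length).
#' Warnings: tip diameter exceeding base diameter, which contradicts
#' tip-to-base widening but can occur in real branches.
#'
#' @param data A branch table (or any data frame with the canonical columns).
#' @return A tibble with columns `row`, `species_id`, `field`, `severity`
#'   (`"error"` or `"warning"`), `message`. Zero rows when the table is
#'   clean.
#' @export
validate_branches <- function(data) {
  data <- suppressWarnings(as_branch_table(
    data, provenance = attr(data, "provenance") %||% "user"))
  issues <- list()
  flag <- function(rows, field, severity, msg) {
    if (!any(rows, na.rm = TRUE)) return(NULL)
    idx <- which(rows | is.na(rows))
    tibble::tibble(row = idx, species_id = data$species_id[idx],
                   field = field, severity = severity, message = msg)
  }
  bad_count <- function(v) !is.finite(v) | v < 1 | v != round(v)
  issues <- dplyr::bind_rows(
    flag(bad_count(data$n_base), "n_base", "error",
         "conduit count must be an integer >= 1"),
    flag(bad_count(data$n_tip), "n_tip", "error",
         "conduit count must be an integer >= 1"),
    flag(!is.finite(data$d_base_um) | data$d_base_um <= 0, "d_base_um",
         "error", "diameter must be > 0"),
    flag(!is.finite(data$d_tip_um) | data$d_tip_um <= 0, "d_tip_um",
         "error", "diameter must be > 0"),
    flag(!is.finite(data$dist_tip_cm) | data$dist_tip_cm <= 0,
         "dist_tip_cm", "error", "apex distance must be > 0"),
    flag(is.finite(data$dist_base_cm) & is.finite(data$dist_tip_cm) &
           data$dist_base_cm <= data$dist_tip_cm, "dist_base_cm", "error",
         "dist_base_cm must exceed dist_tip_cm (segment length > 0)"),
    flag(is.finite(data$d_base_um) & is.finite(data$d_tip_um) &
           data$d_base_um > 0 & data$d_tip_um > data$d_base_um, "d_tip_um",
         "warning", "tip diameter exceeds base diameter (no widening)")
  )
  dup <- duplicated(data$species_id) & !data$branched
  issues <- dplyr::bind_rows(
    issues,
    flag(dup, "species_id", "warning",
         "duplicated species_id on an unbranched record")
  )
  if (is.null(issues) || nrow(issues) == 0) {
    return(tibble::tibble(row = integer(), species_id = character(),
                          field = character(), severity = character(),
                          message = character()))
  }
  dplyr::arrange(issues, .data$row, .data$field)
}

#' Serialize a validation report to JSON
#'
#' @param report Output of [validate_branches()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Segment length of each branch
#'
#' `L_segment = dist_base_cm - dist_tip_cm`, the conductive path length
#' between the two sampled sections, in cm.
#'
#' @param data A branch table.
#' @return Numeric vector.
#' @export
segment_length <- function(data) {
  data$dist_base_cm - data$dist_tip_cm
}

#' Normalize species labels for tree matching
#'
#' Trims and collapses whitespace and converts spaces to underscores, the
#' Newick convention, so trait tables and tip labels join reliably.
#'
#' @param x Character vector of species names.
#' @return Normalized character vector.
#' @export
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  gsub(" ", "_", x)
}
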