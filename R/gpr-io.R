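#' Default control-feature patterns
#'
#' Regular expressions (matched case-insensitively against both the feature ID
#' and name) identifying control spots on a protein array. Commercial arrays
#' print gradient and landing-light features under names like "Alexa Fluor",
#' "Anti-Human IgG", "BSA", "Buffer", "Empty" or an explicit "Control" label;
#' the exact nomenclature varies between array versions, so the list is a
#' configurable argument everywhere it is used.
#'
#' @return Character vector of regular expressions.
#' @export
#' @examples
#' default_control_patterns()
default_control_patterns <- function() {
  c("control", "empty", "buffer", "\\bbsa\\b", "igg", "alexa", "biotin",
    "gst\\b", "v5 ")
}

required_gpr_columns <- function() {
  # canonical label -> accepted header aliases (lower case, quotes stripped)
  list(
    block   = c("block"),
    row     = c("row"),
    column  = c("column"),
    id      = c("id"),
    name    = c("name"),
    f635    = c("f635 median", "f635median", "f635"),
    b635    = c("b635 median", "b635median", "b635"),
    flag    = c("flags", "flag")
  )
}

canonical_gpr_label <- function(key) {
  c(block = "Block", row = "Row", column = "Column", id = "ID", name = "Name",
    f635 = "F635 Median", b635 = "B635 Median", flag = "Flags")[[key]]
}

#' Construct an array scan
#'
#' An `array_scan` bundles the per-spot table of one microarray incubation with
#' its identity: which RNA was probed, on which strand, and how many printing
#' blocks (sub-arrays) the slide has. It is the unit of input for
#' quantification and hit calling.
#'
#' @param spots Data frame with columns `block`, `row`, `column` (1-based grid
#'   position), `protein_id`, `protein_name`, `f635` (foreground median
#'   intensity at 635 nm), `b635` (local background median), `flag` (scanner
#'   quality flag; negative means bad) and `is_control`.
#' @param scan_id Identifier for the scan.
#' @param rna_id Identifier of the probed RNA locus (or `NA`).
#' @param strand `"sense"`, `"antisense"` or `NA`.
#' @param n_blocks Number of printing blocks; defaults to the maximum `block`.
#' @return An `array_scan` object.
#' @export
#' @examples
#' sp <- tibble::tibble(
#'   block = 1, row = 1, column = 1:2, protein_id = "P1",
#'   protein_name = "protein 1", f635 = c(900, 950), b635 = c(300, 310),
#'   flag = 0L, is_control = FALSE
#' )
#' array_scan(sp, scan_id = "demo", rna_id = "TP53", strand = "sense")
array_scan <- function(spots, scan_id = "scan", rna_id = NA_character_,
                       strand = NA_character_, n_blocks = NULL) {
  spots <- as_tibble(spots)
  needed <- c("block", "row", "column", "protein_id", "protein_name",
              "f635", "b635", "flag", "is_control")
  missing <- setdiff(needed, names(spots))
  if (length(missing) > 0) {
    stop_input(paste0("`spots` is missing column(s): ",
                      paste(missing, collapse = ", ")))
  }
  spots$protein_id <- as.character(spots$protein_id)
  spots$protein_name <- as.character(spots$protein_name)
  spots$flag <- as.integer(spots$flag)
  for (col in c("f635", "b635")) {
    v <- spots[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop_input(sprintf("`%s` must be finite and >= 0 for every spot.", col))
    }
  }
  key <- paste(spots$block, spots$row, spots$column)
  if (anyDuplicated(key) > 0) {
    dup <- key[duplicated(key)][1]
    stop_format(sprintf("duplicate spot coordinates (block row column): %s", dup))
  }
  if (!is.na(strand) && !strand %in% c("sense", "antisense")) {
    stop_input('`strand` must be "sense", "antisense" or NA.')
  }
  structure(
    list(
      spots = spots[needed],
      scan_id = as.character(scan_id),
      rna_id = as.character(rna_id),
      strand = as.character(strand),
      n_blocks = as.integer(n_blocks %||%
                              (if (nrow(spots)) max(spots$block) else 0L))
    ),
    class = "array_scan"
  )
}

#' @export
print.array_scan <- function(x, ...) {
  cat(sprintf(
    "<array_scan> %s  rna: %s (%s)  %d spots, %d blocks, %d control spots\n",
    x$scan_id, x$rna_id, x$strand, nrow(x$spots), x$n_blocks,
    sum(x$spots$is_control)
  ))
  print(x$spots, n = 5)
  invisible(x)
}

is_array_scan <- function(x) inherits(x, "array_scan")

scan_spots <- function(x, arg = "x") {
  if (is_array_scan(x)) return(x$spots)
  if (inherits(x, "data.frame")) return(as_tibble(x))
  stop_input(sprintf("`%s` must be an array_scan or a spot data frame.", arg))
}

strip_quotes <- function(x) gsub('^"|"$', "", x)

#' Read a GenePix Results (GPR/ATF) file
#'
#' Parses the Axon Text Format used by GenePix: an `ATF 1.0` magic line, a line
#' with the counts of optional header records and data columns, the optional
#' `"Key=Value"` records, then a tab-delimited table. Only the columns needed
#' for signal-over-background analysis are required (Block, Row, Column, ID,
#' Name, F635 Median, B635 Median, Flags); header matching is case-insensitive
#' and tolerant of quoting. Scans written by [write_gpr()] carry the scan
#' identity (`ScanId`, `RnaId`, `Strand`, `Blocks`) in optional header records
#' and these are restored unless overridden by the arguments.
#'
#' @param path Path to a `.gpr` file.
#' @param control_patterns Regular expressions marking control features; a spot
#'   is a control when its ID or name matches any pattern (case-insensitive).
#' @param scan_id,rna_id,strand Optional overrides for the scan identity.
#' @return An [array_scan()].
#' @seealso [write_gpr()], [pair_duplicates()]
#' @export
read_gpr <- function(path, control_patterns = default_control_patterns(),
                     scan_id = NULL, rna_id = NULL, strand = NULL) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || !grepl("^ATF[\t ]1\\.0\\s*$", lines[1])) {
    stop_format("not an ATF 1.0 file: first line must be 'ATF 1.0'.")
  }
  counts <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  if (length(counts) < 2 || any(is.na(counts[1:2]))) {
    stop_format("malformed ATF header: line 2 must give record and field counts.")
  }
  n_header <- counts[1]
  meta <- list()
  if (n_header > 0) {
    recs <- strip_quotes(lines[2 + seq_len(n_header)])
    kv <- regmatches(recs, regexec("^([^=]+)=(.*)$", recs))
    for (m in kv) {
      if (length(m) == 3 && nzchar(trimws(m[3]))) {
        meta[[trimws(m[2])]] <- trimws(m[3])
      }
    }
  }
  body <- lines[-seq_len(2 + n_header)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1) stop_format("ATF file has no column header row.")
  tab <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                    quote = '"', check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  header_low <- tolower(trimws(names(tab)))

  cols <- required_gpr_columns()
  idx <- vapply(names(cols), function(key) {
    hit <- which(header_low %in% cols[[key]])
    if (length(hit) == 0) {
      stop_format(sprintf("required column missing: '%s'", canonical_gpr_label(key)))
    }
    hit[1]
  }, integer(1))

  parse_num <- function(key) {
    raw <- trimws(tab[[idx[[key]]]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & nzchar(raw))
    if (length(bad) > 0 || anyNA(val)) {
      row <- if (length(bad) > 0) bad[1] else which(is.na(val))[1]
      stop_format(sprintf(
        "non-numeric value in column '%s' at data row %d: '%s'",
        canonical_gpr_label(key), row, raw[row]
      ))
    }
    val
  }

  id <- strip_quotes(tab[[idx[["id"]]]])
  name <- strip_quotes(tab[[idx[["name"]]]])
  is_ctrl <- rep(FALSE, length(id))
  for (pat in control_patterns) {
    is_ctrl <- is_ctrl | grepl(pat, id, ignore.case = TRUE) |
      grepl(pat, name, ignore.case = TRUE)
  }

  spots <- tibble(
    block = as.integer(parse_num("block")),
    row = as.integer(parse_num("row")),
    column = as.integer(parse_num("column")),
    protein_id = id,
    protein_name = name,
    f635 = parse_num("f635"),
    b635 = parse_num("b635"),
    flag = as.integer(parse_num("flag")),
    is_control = is_ctrl
  )
  array_scan(
    spots,
    scan_id = scan_id %||% meta[["ScanId"]] %||%
      sub("\\.gpr$", "", basename(path), ignore.case = TRUE),
    rna_id = rna_id %||% meta[["RnaId"]] %||% NA_character_,
    strand = strand %||% meta[["Strand"]] %||% NA_character_,
    n_blocks = as.integer(meta[["Blocks"]] %||%
                            (if (nrow(spots)) max(spots$block) else 0L))
  )
}

#' Write an array scan as a GPR/ATF file
#'
#' Emits a tab-delimited ATF 1.0 file that [read_gpr()] parses back
#' bit-exactly for all required columns; the scan identity is stored in
#' optional header records so a round trip also restores `rna_id`, `strand`,
#' `scan_id` and `n_blocks`.
#'
#' @param scan An [array_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gpr <- function(scan, path) {
  if (!is_array_scan(scan)) stop_input("`scan` must be an array_scan.")
  sp <- scan$spots
  header <- c(
    "ATF\t1.0",
    "5\t8",
    '"Type=GenePix Results 3"',
    sprintf('"ScanId=%s"', scan$scan_id),
    sprintf('"RnaId=%s"', if (is.na(scan$rna_id)) "" else scan$rna_id),
    sprintf('"Strand=%s"', if (is.na(scan$strand)) "" else scan$strand),
    sprintf('"Blocks=%d"', scan$n_blocks),
    paste(sprintf('"%s"', c("Block", "Row", "Column", "ID", "Name",
                            "F635 Median", "B635 Median", "Flags")),
          collapse = "\t")
  )
  num <- function(x) sprintf("%.17g", x)
  rows <- if (nrow(sp) == 0) character(0) else {
    paste(sp$block, sp$row, sp$column,
          sprintf('"%s"', sp$protein_id), sprintf('"%s"', sp$protein_name),
          num(sp$f635), num(sp$b635), sp$flag, sep = "\t")
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop_input(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Group duplicate spots by protein
#'
#' Arrays print every protein in duplicate; this collects the spots of each
#' non-control protein in deterministic (block, row, column) order. Proteins
#' represented by a number of spots other than two (damaged or degenerate
#' layouts) are reported with a warning and kept with the spots available.
#'
#' @param scan An [array_scan()] or spot data frame.
#' @return A tibble with one row per non-control protein: `protein_id`,
#'   `n_spots` and a `spots` list-column of spot tibbles. The IDs of
#'   non-duplicate proteins are attached as attribute `"singletons"`.
#' @export
pair_duplicates <- function(scan) {
  sp <- scan_spots(scan, "scan")
  sp <- sp[!sp$is_control, , drop = FALSE]
  if (nrow(sp) == 0) {
    stop_input("scan contains no non-control protein spots.")
  }
  sp <- arrange(sp, .data$protein_id, .data$block, .data$row, .data$column)
  nested <- tidyr::nest(sp, spots = -"protein_id")
  nested <- mutate(nested, n_spots = vapply(.data$spots, nrow, integer(1)))
  odd <- nested$protein_id[nested$n_spots != 2L]
  if (length(odd) > 0) {
    warn(sprintf("%d protein(s) not spotted exactly twice: %s",
                 length(odd), compact_ids(odd)),
         class = "rbpscreen_duplicate_warning")
  }
  out <- nested[, c("protein_id", "n_spots", "spots")]
  attr(out, "singletons") <- odd
  out
}
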