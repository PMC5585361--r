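#' Screen layout configuration
#'
#' Describes how a well table maps onto the screening design: which string
#' marks DMSO control wells, which fluorescence/luminescence channel reports
#' which cell line, and how many DMSO wells a plate must carry before its
#' control median is trusted.
#'
#' @param dmso_sentinel Compound id used for DMSO control wells.
#' @param channels Named character vector mapping channel (e.g. `"GFP"`) to a
#'   cell-line label (e.g. `"HN137-Pri"`).
#' @param min_dmso_wells Minimum DMSO wells required per plate per channel.
#' @return An object of class `screen_layout`.
#' @examples
#' screen_layout(channels = c(GFP = "HN137-Pri", RFP = "HN137-Met"))
#' @export
screen_layout <- function(dmso_sentinel = "DMSO",
                          channels = c(GFP = "HN137-Pri", RFP = "HN137-Met"),
                          min_dmso_wells = 8) {
  stopifnot(is.character(dmso_sentinel), length(dmso_sentinel) == 1L,
            is.character(channels), !is.null(names(channels)),
            min_dmso_wells >= 1)
  structure(list(dmso_sentinel = dmso_sentinel,
                 channels = channels,
                 min_dmso_wells = as.integer(min_dmso_wells)),
            class = "screen_layout")
}

#' Normalize a well label
#'
#' Well labels are accepted case-insensitively and zero-padded, so `"a1"`,
#' `"A1"` and `"A01"` all denote the same well.
#'
#' @param well Character vector of well labels (row letter + column number).
#' @return Canonical labels, e.g. `"A01"`.
#' @export
normalize_well_label <- function(well) {
  well <- toupper(trimws(as.character(well)))
  ok <- grepl("^[A-P][0-9]{1,2}$", well)
  if (any(!ok)) {
    stop("malformed well label(s): ", paste(unique(well[!ok]), collapse = ", "))
  }
  row <- substr(well, 1, 1)
  col <- as.integer(substring(well, 2))
  if (any(col < 1 | col > 24)) stop("well column out of range 1-24")
  sprintf("%s%02d", row, col)
}

screen_required_cols <- c("plate_id", "well", "compound_id", "concentration",
                          "channel", "signal", "role")

#' Construct and validate a screen dataset
#'
#' The canonical in-memory form of one screen: a long (one row per well per
#' channel) well table, a compound annotation table, and the channel-to-line
#' mapping taken from the layout. All invariants are checked on construction:
#' non-negative signals, unique (plate, well, channel) triples, DMSO wells
#' carrying the sentinel id, and a minimum number of DMSO control wells per
#' plate per channel.
#'
#' @param wells data.frame with columns `plate_id`, `well`, `compound_id`,
#'   `concentration`, `channel`, `signal`, `role`.
#' @param compounds data.frame with columns `compound_id`, `name`,
#'   `target_class` (may carry extra columns).
#' @param layout A [screen_layout()].
#' @return An object of class `screen_dataset`.
#' @export
screen_dataset <- function(wells, compounds = NULL, layout = screen_layout()) {
  stopifnot(is.data.frame(wells))
  missing_cols <- setdiff(screen_required_cols, names(wells))
  if (length(missing_cols)) {
    stop("well table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  wells$well <- normalize_well_label(wells$well)
  wells$signal <- as.numeric(wells$signal)
  wells$concentration <- suppressWarnings(as.numeric(wells$concentration))

  if (any(!is.finite(wells$signal))) stop("non-finite signal value(s) in well table")
  if (any(wells$signal < 0)) {
    stop("negative signal value(s): signals are arbitrary fluorescence units and must be >= 0")
  }
  if (!all(wells$role %in% c("compound", "dmso_control"))) {
    stop("role must be 'compound' or 'dmso_control'")
  }
  bad_chan <- setdiff(unique(wells$channel), names(layout$channels))
  if (length(bad_chan)) {
    stop("channel(s) not declared in layout: ", paste(bad_chan, collapse = ", "))
  }
  key <- paste(wells$plate_id, wells$well, wells$channel, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- wells[duplicated(key), , drop = FALSE]
    stop("duplicate (plate, well, channel) measurement(s), e.g. plate ",
         dup$plate_id[1], " well ", dup$well[1], " channel ", dup$channel[1])
  }
  ctrl <- wells$role == "dmso_control"
  if (any(wells$compound_id[ctrl] != layout$dmso_sentinel)) {
    stop("dmso_control wells must carry the DMSO sentinel compound id '",
         layout$dmso_sentinel, "'")
  }
  # per plate/channel control-well count gate, so the DMSO median is trusted
  cnt <- table(wells$plate_id[ctrl], wells$channel[ctrl])
  plates <- unique(wells$plate_id)
  for (p in plates) {
    for (ch in unique(wells$channel)) {
      n <- if (as.character(p) %in% rownames(cnt) && ch %in% colnames(cnt))
        cnt[as.character(p), ch] else 0L
      if (n < layout$min_dmso_wells) {
        stop("plate '", p, "' channel ", ch, " has ", n,
             " DMSO control wells; at least ", layout$min_dmso_wells,
             " are required")
      }
    }
  }
  if (is.null(compounds)) {
    ids <- sort(unique(wells$compound_id[!ctrl]))
    compounds <- data.frame(compound_id = ids, name = ids,
                            target_class = NA_character_,
                            stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unique(wells$compound_id[!ctrl]), compounds$compound_id)
  if (length(unknown)) {
    stop("compound well(s) reference id(s) absent from the compound table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  structure(list(wells = wells, compounds = compounds,
                 lines = layout$channels, layout = layout),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("screen_dataset:", length(unique(x$wells$plate_id)), "plate(s),",
      nrow(x$wells), "well measurements,",
      sum(x$wells$role == "compound"), "compound wells,",
      length(unique(x$wells$compound_id[x$wells$role == "compound"])),
      "compounds,", length(x$lines), "channel(s)\n")
  for (ch in names(x$lines)) cat("  ", ch, "->", x$lines[[ch]], "\n")
  invisible(x)
}

#' Read a long-format screen well table
#'
#' Reads the canonical tidy CSV/TSV form (one row per well per channel) and
#' validates it into a [screen_dataset()].
#'
#' @param path CSV or TSV file with the well columns (`plate_id`, `well`,
#'   `compound_id`, `concentration`, `channel`, `signal`, `role`).
#' @param layout A [screen_layout()] naming the DMSO sentinel and the
#'   channel-to-line mapping.
#' @param compounds Optional compound annotation table (data.frame or CSV path).
#' @return A validated `screen_dataset`.
#' @export
read_screen_table <- function(path, layout = screen_layout(), compounds = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(compounds) && length(compounds) == 1L) {
    compounds <- utils::read.csv(compounds, stringsAsFactors = FALSE,
                                 comment.char = "#")
  }
  screen_dataset(tab, compounds = compounds, layout = layout)
}

#' Write a screen dataset back to its canonical long CSV form
#'
#' @param ds A `screen_dataset`.
#' @param path Output CSV path.
#' @param header Optional character vector of `#`-prefixed metadata lines.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(ds, path, header = NULL) {
  stopifnot(inherits(ds, "screen_dataset"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(ds$wells, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a 16 x 24 plate-matrix export to the long well form
#'
#' Instrument exports often come as one matrix per plate per channel (rows
#' A..P, columns 1..24). This reshapes such a matrix into rows of the long
#' well table; compound identity and role must be supplied via a plate map
#' with the same shape.
#'
#' @param signal_matrix 16 x 24 numeric matrix of signals.
#' @param compound_matrix 16 x 24 character matrix of compound ids (the DMSO
#'   sentinel marks control wells).
#' @param plate_id,channel Scalars identifying the plate and channel.
#' @param dmso_sentinel DMSO id string used in `compound_matrix`.
#' @return data.frame in long well-table form.
#' @export
plate_matrix_to_long <- function(signal_matrix, compound_matrix, plate_id,
                                 channel, dmso_sentinel = "DMSO") {
  stopifnot(identical(dim(signal_matrix), c(16L, 24L)),
            identical(dim(compound_matrix), c(16L, 24L)))
  rows <- LETTERS[1:16]
  well <- as.vector(outer(rows, 1:24, function(r, c) sprintf("%s%02d", r, c)))
  cmpd <- as.vector(compound_matrix)
  data.frame(plate_id = plate_id, well = well, compound_id = cmpd,
             concentration = NA_real_, channel = channel,
             signal = as.vector(signal_matrix),
             role = ifelse(cmpd == dmso_sentinel, "dmso_control", "compound"),
             stringsAsFactors = FALSE)
}

#' Build a gene-set collection restricted to a measurement universe
#'
#' Sets are intersected with the universe of genes measured on the platform;
#' sets that become empty after intersection are dropped with a warning.
#' Duplicate genes within a set are collapsed.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Character vector of gene ids measured on the platform.
#' @return Object of class `gene_set_collection` with elements `sets` and
#'   `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)), is.character(universe))
  universe <- unique(universe)
  sets <- lapply(sets, function(g) unique(intersect(as.character(g), universe)))
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) empty after intersection with the ",
            "universe were dropped: ",
            paste(utils::head(names(sets)[empty], 5), collapse = ", "))
    sets <- sets[!empty]
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @param universe Optional measurement universe; defaults to the union of all
#'   listed genes.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(structure(list(), names = character(0)),
                               universe = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L)) {
    stop("GMT format error at line ", which(nf < 3L)[1],
         ": fewer than 3 tab-separated fields")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set name(s) in GMT file")
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  gene_set_collection(sets, universe)
}

#' Read and validate a caliper-measurement table
#'
#' Expects columns `animal_id`, `arm`, `day`, `length`, `width` (mm). Rows
#' where width exceeds length are swapped with a warning; every animal must
#' have a day-0 record.
#'
#' @param path CSV path, or a data.frame already in that shape.
#' @return data.frame of validated caliper records.
#' @export
read_caliper_table <- function(path) {
  tab <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("input file not found: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  }
  need <- c("animal_id", "arm", "day", "length", "width")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("caliper table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$day <- as.integer(tab$day)
  tab$length <- as.numeric(tab$length)
  tab$width <- as.numeric(tab$width)
  if (any(tab$length <= 0 | tab$width <= 0)) {
    stop("caliper dimensions must be positive")
  }
  swap <- tab$width > tab$length
  if (any(swap)) {
    warning(sum(swap), " record(s) had width > length; dimensions swapped")
    tmp <- tab$length[swap]
    tab$length[swap] <- tab$width[swap]
    tab$width[swap] <- tmp
  }
  key <- paste(tab$animal_id, tab$day)
  if (anyDuplicated(key)) {
    stop("duplicate measurement for animal/day: ", key[duplicated(key)][1])
  }
  has0 <- tapply(tab$day, tab$animal_id, function(d) any(d == 0L))
  if (any(!has0)) {
    stop("animal(s) without a day-0 measurement: ",
         paste(names(has0)[!has0], collapse = ", "))
  }
  tab[order(tab$animal_id, tab$day), , drop = FALSE]
}

#' Cohort model take rates
#'
#' Desk arithmetic for model-establishment ("take") rates: the percentage of
#' attempts that yielded an established model, e.g. xenograft models per
#' grafted tumour sample, or patients with at least one model per enrolled
#' patient.
#'
#' @param n_success Number of successful establishments.
#' @param n_total Number of attempts.
#' @return Take rate in percent.
#' @examples
#' take_rate(25, 43)  # ~58.1
#' take_rate(20, 24)  # ~83.3
#' @export
take_rate <- function(n_success, n_total) {
  stopifnot(n_total > 0, n_success >= 0, n_success <= n_total)
  100 * n_success / n_total
}
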