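# Model-frame domain alignment, per-column conservation and
# DNA-binding class prediction from basic-region residues.

#' Project a domain hit onto the model frame
#'
#' Returns the 79-character (model length) string whose column `c` holds
#' the protein residue aligned to model column `c`, `-` where the hit
#' deletes the column or does not reach it.  Insertions relative to the
#' model are discarded.
#'
#' @param hit one row of a [scan_sequence()] result (data.frame row or
#'   list with `alignment`).
#' @param protein the protein sequence the hit refers to.
#' @param model_length number of model columns.
#' @return model-frame string.
#' @export
align_to_model <- function(hit, protein, model_length = BHLH_MODEL_LENGTH) {
  aln <- if (is.data.frame(hit)) hit$alignment[[1]] else hit$alignment
  if (is.null(aln)) stop("hit carries no model-column alignment",
                         call. = FALSE)
  res <- strsplit(protein, "")[[1]]
  out <- rep("-", model_length)
  out[aln[, "model_col"]] <- res[aln[, "seq_pos"]]
  paste(out, collapse = "")
}

#' Model-frame alignment for a validated member set
#'
#' @param members data.frame from [filter_and_dedup()] or
#'   [identify_family()] (uses `name` when present, else `protein_id`).
#' @param proteins named character vector or `AAStringSet`.
#' @param model_length number of model columns.
#' @return named character vector: member -> model-frame string.
#' @export
domain_alignment <- function(members, proteins,
                             model_length = BHLH_MODEL_LENGTH) {
  proteins <- as_named_character(proteins)
  rows <- vapply(seq_len(nrow(members)), function(i) {
    align_to_model(list(alignment = members$alignment[[i]]),
                   proteins[[members$protein_id[i]]], model_length)
  }, character(1))
  names(rows) <- if (!is.null(members$name)) members$name else
    members$protein_id
  rows
}

#' Per-column consensus profile of a domain alignment
#'
#' For every model column the consensus residue is the most frequent
#' non-gap residue (ties broken alphabetically) and the consensus ratio
#' is its count divided by the number of rows (gap rows count in the
#' denominator).  Calls use strict comparisons: ratio > 0.5 is "highly"
#' and ratio > 0.75 "extremely" conserved.
#'
#' @param alignment named character vector of model-frame strings
#'   (equal length, `-` gaps allowed).
#' @param regions data.frame with `region`, `start`, `end` partitioning
#'   the columns; defaults to the basic/helix1/loop/helix2 annotation.
#' @return data.frame with one row per column: `pos`, `residue`,
#'   `ratio`, `region`, `highly` (>50%), `extremely` (>75%).
#' @export
build_consensus <- function(alignment, regions = BHLH_REGIONS) {
  alignment <- as_named_character(alignment)
  if (length(alignment) < 1) stop("alignment is empty", call. = FALSE)
  w <- unique(nchar(alignment))
  if (length(w) != 1) stop("alignment rows differ in length", call. = FALSE)
  mat <- do.call(rbind, strsplit(alignment, ""))
  n <- nrow(mat)
  region_of <- rep(NA_character_, w)
  for (i in seq_len(nrow(regions))) {
    region_of[regions$start[i]:min(regions$end[i], w)] <- regions$region[i]
  }
  out <- lapply(seq_len(w), function(c) {
    col <- mat[, c]
    col <- col[col != "-"]
    if (!length(col)) {
      return(data.frame(pos = c, residue = NA_character_, ratio = 0,
                        region = region_of[c], stringsAsFactors = FALSE))
    }
    counts <- sort(table(col), decreasing = TRUE)
    top <- max(counts)
    res <- sort(names(counts)[counts == top])[1]   # alphabetical tie-break
    data.frame(pos = c, residue = res, ratio = top / n,
               region = region_of[c], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$highly <- out$ratio > 0.5
  out$extremely <- out$ratio > 0.75
  out
}

#' Conserved residues at the 50% and 75% thresholds
#'
#' @param profile consensus profile from [build_consensus()].
#' @return list with data.frames `highly` and `extremely`, each holding
#'   `pos` and `residue` sorted by position; the extremely conserved set
#'   is a subset of the highly conserved one.
#' @export
call_conserved_residues <- function(profile) {
  hi <- profile[profile$highly, c("pos", "residue")]
  ex <- profile[profile$extremely, c("pos", "residue")]
  rownames(hi) <- rownames(ex) <- NULL
  list(highly = hi[order(hi$pos), ], extremely = ex[order(ex$pos), ])
}

#' Predict DNA-binding class from basic-region residues
#'
#' Classes are decided solely from model positions 9, 13, 16 and 17.
#' The E-box core requires Glu-13 and Arg-16 together; a G-box binder
#' additionally carries His or Lys at 9 and Arg at 17.  Sequences whose
#' Glu-13/Arg-16 pair is broken are non-E-box binders.  A gap at a
#' tested position fails that position's test.
#'
#' @param row model-frame string of length 79 (or the model length).
#' @param model_length expected string length.
#' @return list with `residues` (named character at positions 9/13/16/17)
#'   and `class` (`"G-box"`, `"E-box"` or `"non-E-box"`).
#' @export
classify_binding <- function(row, model_length = BHLH_MODEL_LENGTH) {
  if (!is.character(row) || length(row) != 1 ||
      nchar(row) != model_length) {
    stop("model-frame row must be a single string of length ",
         model_length, call. = FALSE)
  }
  res <- strsplit(row, "")[[1]][BINDING_POSITIONS]
  names(res) <- BINDING_POSITIONS
  e_core <- identical(res[["13"]], "E") && identical(res[["16"]], "R")
  cls <- if (e_core && res[["9"]] %in% c("H", "K") &&
             identical(res[["17"]], "R")) {
    "G-box"
  } else if (e_core) {
    "E-box"
  } else {
    "non-E-box"
  }
  list(residues = res, class = cls)
}

#' Binding-class census of an aligned member set
#'
#' @param alignment named character vector of model-frame rows.
#' @return list with `calls` (data.frame: member, residues at 9/13/16/17,
#'   class) and `census` (named counts over the three classes, summing to
#'   the number of members).
#' @export
binding_census <- function(alignment) {
  alignment <- as_named_character(alignment)
  if (!length(alignment)) stop("no members to classify", call. = FALSE)
  calls <- lapply(alignment, classify_binding,
                  model_length = nchar(alignment[[1]]))
  df <- data.frame(
    member = names(alignment),
    res9 = vapply(calls, function(x) x$residues[["9"]], character(1)),
    res13 = vapply(calls, function(x) x$residues[["13"]], character(1)),
    res16 = vapply(calls, function(x) x$residues[["16"]], character(1)),
    res17 = vapply(calls, function(x) x$residues[["17"]], character(1)),
    class = vapply(calls, `[[`, character(1), "class"),
    stringsAsFactors = FALSE, row.names = NULL)
  census <- table(factor(df$class, levels = c("G-box", "E-box",
                                              "non-E-box")))
  list(calls = df, census = stats::setNames(as.integer(census),
                                            names(census)))
}
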