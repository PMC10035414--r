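# Small shared helpers.

#' Order chromosome labels naturally
#'
#' Orders labels such as `chr2`, `chr10` by the numeric part of the name
#' (so `chr2` precedes `chr10`); labels without a numeric part sort after
#' numeric ones, alphabetically.
#'
#' @param labels character vector of chromosome names.
#' @return integer permutation ordering `labels`.
#' @export
order_chromosomes <- function(labels) {
  num <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", labels)))
  has_num <- !is.na(num)
  order(!has_num, num, labels)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Split protein sequences (character vector) into residue matrices is
# done ad hoc; this checks the amino-acid alphabet.
check_protein <- function(seq, id = "protein") {
  if (!nzchar(seq)) stop("empty sequence for ", id, call. = FALSE)
  bad <- setdiff(strsplit(seq, "")[[1]], c(AA20, "X"))
  if (length(bad)) {
    stop("invalid residue(s) in ", id, ": ",
         paste(unique(bad), collapse = ","), call. = FALSE)
  }
  invisible(TRUE)
}

# Round half away from zero to `digits` decimals (the convention used
# for reported percentages; base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Named character vector from an AAStringSet/DNAStringSet or pass-through.
as_named_character <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    out
  } else if (is.character(x)) {
    x
  } else {
    stop("expected a character vector or an XStringSet", call. = FALSE)
  }
}
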