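#' Parse a telomeric sequence in lowercase-r substitution notation
#'
#' Telomeric constructs are written 5'->3' as plain A/C/G/T with an embedded
#' ribonucleotide marked by a lowercase `r` immediately before the substituted
#' base, e.g. `"TTArGGGTTAGGGTTAGGGTTAGGG"` for a ribo-G at position 4 of the
#' 24-mer. The `r` is a prefix modifier: it consumes no sequence position, so
#' construct names such as TELR4 index the plain base string.
#'
#' @param text Sequence string. Only `A`, `C`, `G`, `T` and at most one
#'   lowercase `r` are allowed; the `r` must immediately precede a base.
#' @param name Optional label carried on the returned object.
#' @return A `telomere_seq` object: a list with `name`, `bases` (character
#'   vector), `sugar` (`"deoxy"` or `"ribo"` per residue), and `length`.
#' @examples
#' s <- parse_telomere_seq("TTArGGGTTAGGGTTAGGGTTAGGG", name = "TELR4")
#' which(s$sugar == "ribo")
#' @export
parse_telomere_seq <- function(text, name = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) {
    stop("empty sequence string", call. = FALSE)
  }
  bad <- which(!chars %in% c("A", "C", "G", "T", "r"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid character '%s' at string index %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  r_idx <- which(chars == "r")
  if (length(r_idx) > 1L) {
    stop(sprintf("more than one 'r' marker (string indices %s); at most one ribonucleotide is supported",
                 paste(r_idx, collapse = ", ")), call. = FALSE)
  }
  if (length(r_idx) == 1L) {
    if (r_idx == length(chars)) {
      stop(sprintf("trailing 'r' at string index %d has no base to modify", r_idx),
           call. = FALSE)
    }
    if (chars[r_idx + 1L] == "r") {
      stop(sprintf("'r' at string index %d is followed by another 'r'", r_idx),
           call. = FALSE)
    }
  }
  base_mask <- chars != "r"
  bases <- chars[base_mask]
  sugar <- rep("deoxy", length(bases))
  if (length(r_idx) == 1L) {
    # position of the modified base in the base-only string
    ribo_pos <- sum(base_mask[seq_len(r_idx)]) + 1L
    sugar[ribo_pos] <- "ribo"
  }
  new_telomere_seq(name = name, bases = bases, sugar = sugar)
}

new_telomere_seq <- function(name, bases, sugar) {
  stopifnot(length(bases) == length(sugar),
            all(bases %in% c("A", "C", "G", "T")),
            all(sugar %in% c("deoxy", "ribo")),
            sum(sugar == "ribo") <= 1L)
  structure(
    list(name = name, bases = bases, sugar = sugar, length = length(bases)),
    class = "telomere_seq"
  )
}

#' Format a telomeric sequence back to lowercase-r notation
#'
#' Round-trip inverse of [parse_telomere_seq()]: for any valid object,
#' `parse_telomere_seq(format_telomere_seq(s))` reproduces `s` exactly.
#'
#' @param seq A `telomere_seq` object.
#' @return A single string.
#' @export
format_telomere_seq <- function(seq) {
  stopifnot(inherits(seq, "telomere_seq"))
  out <- seq$bases
  ribo <- which(seq$sugar == "ribo")
  if (length(ribo) == 1L) {
    out[ribo] <- paste0("r", out[ribo])
  }
  paste(out, collapse = "")
}

#' @export
print.telomere_seq <- function(x, ...) {
  cat(sprintf("<telomere_seq%s> %s (%d nt, %s)\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              format_telomere_seq(x), x$length,
              if (any(x$sugar == "ribo")) {
                sprintf("ribo at %d", which(x$sugar == "ribo"))
              } else "all-DNA"))
  invisible(x)
}

#' Repeat position class of a 24-mer telomeric position
#'
#' Within each TTAGGG repeat the offsets map to: T, T, A (loop), G1, G2, G3.
#' Classes follow the convention used for the construct panel: position 3
#' (the A of the first TTA) is grouped with the loop-A class even though it
#' precedes the first tetrad in the folded structure.
#'
#' @param position 1-based position(s) in the 24-mer.
#' @return Character vector of classes among `"T"`, `"A_loop"`, `"G1"`,
#'   `"G2"`, `"G3"`.
#' @examples
#' telomere_position_class(c(4, 9, 23))
#' @export
telomere_position_class <- function(position) {
  stopifnot(is.numeric(position), all(position >= 1))
  offset <- (as.integer(position) - 1L) %% 6L
  c("T", "T", "A_loop", "G1", "G2", "G3")[offset + 1L]
}

#' Locate and classify the ribonucleotide substitution of a canonical 24-mer
#'
#' @param seq A `telomere_seq` of canonical length 24 whose base string is
#'   four tandem copies of TTAGGG.
#' @return A `substitution_site` object: list with `position` (1-based, `NA`
#'   if the sequence carries no substitution), `repeat_index` (1-4), and
#'   `position_class` (`"T"`, `"A_loop"`, `"G1"`, `"G2"`, `"G3"`, or `"none"`).
#' @examples
#' classify_substitution(parse_telomere_seq("TTArGGGTTAGGGTTAGGGTTAGGG"))
#' @export
classify_substitution <- function(seq) {
  stopifnot(inherits(seq, "telomere_seq"))
  if (seq$length != 24L) {
    stop(sprintf("non-canonical sequence length %d (expected 24)", seq$length),
         call. = FALSE)
  }
  if (paste(seq$bases, collapse = "") != strrep("TTAGGG", 4L)) {
    stop("base string is not four tandem copies of TTAGGG", call. = FALSE)
  }
  ribo <- which(seq$sugar == "ribo")
  if (length(ribo) == 0L) {
    site <- list(position = NA_integer_, repeat_index = NA_integer_,
                 position_class = "none")
  } else {
    site <- list(position = ribo,
                 repeat_index = (ribo - 1L) %/% 6L + 1L,
                 position_class = telomere_position_class(ribo))
  }
  structure(site, class = "substitution_site")
}

#' @export
print.substitution_site <- function(x, ...) {
  if (x$position_class == "none") {
    cat("<substitution_site> none (all-DNA)\n")
  } else {
    cat(sprintf("<substitution_site> position %d, repeat %d, class %s\n",
                x$position, x$repeat_index, x$position_class))
  }
  invisible(x)
}

#' Read sequences from a plain-text file
#'
#' One sequence per line in lowercase-r notation, with an optional leading
#' tab-separated name column. Blank lines and lines starting with `#` are
#' skipped.
#'
#' @param path File path.
#' @return Named list of `telomere_seq` objects (names empty when absent).
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) {
      parse_telomere_seq(parts[2], name = parts[1])
    } else {
      parse_telomere_seq(parts[1])
    }
  })
  names(out) <- vapply(out, function(s) s$name %||% "", character(1))
  out
}

#' Write sequences to a plain-text file
#'
#' @param seqs List of `telomere_seq` objects.
#' @param path File path.
#' @export
write_sequences <- function(seqs, path) {
  lines <- vapply(seqs, function(s) {
    if (is.null(s$name)) format_telomere_seq(s)
    else paste(s$name, format_telomere_seq(s), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
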