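#' Phosphopeptide sequence notation
#'
#' The canonical text form for phosphoresidues is the lowercase letter
#' (`s`, `t`, `y`) inside an otherwise uppercase one-letter sequence:
#' lossless, greppable, and trivially parsed. `normalize_phospho()` also
#' accepts the two other common dialects, `pS`-prefix (`LGAKKKpTPLAAVSA`)
#' and parenthetical (`LGAKKKT(ph)PLAAVSA`), and converts them to canonical
#' form.
#'
#' @param sequence character vector of peptide sequences in any supported
#'   notation.
#' @return character vector in canonical lowercase notation.
#' @export
#' @examples
#' normalize_phospho("LGAKKKpTPLAAVSA")
#' normalize_phospho("LGAKKKT(ph)PLAAVSA")
normalize_phospho <- function(sequence) {
  out <- stringr::str_replace_all(sequence, "([STY])\\(ph\\)",
                                  function(m) tolower(substr(m, 1, 1)))
  out <- stringr::str_replace_all(out, "p([STY])",
                                  function(m) tolower(substr(m, 2, 2)))
  out
}

#' Phosphorylated positions of a canonical sequence
#'
#' @param sequence a single canonical-notation sequence.
#' @return integer vector of 1-based positions carrying a phosphogroup.
#' @export
phospho_positions <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  which(chars %in% c("s", "t", "y"))
}

#' Build a peptide library specification
#'
#' A library is expanded from a template string in which `Z` marks the single
#' phosphoacceptor slot and `X` marks variable positions. Each `X` position
#' must be given an allowed residue set; the acceptor slot expands over
#' `acceptor_options`.
#'
#' @param template template string, e.g. `"LGAAXXZXLAAVSA"`.
#' @param residue_sets named list mapping template position (as character or
#'   integer) to a character vector of allowed residues.
#' @param acceptor_options subset of `c("pS", "pT")`.
#' @param max_peptides optional cap: expansion is truncated (in its stable
#'   lexicographic order) to this many peptides.
#' @return a `library_spec` list.
#' @export
library_spec <- function(template, residue_sets = list(),
                         acceptor_options = c("pS", "pT"),
                         max_peptides = Inf) {
  chars <- strsplit(template, "")[[1]]
  z_pos <- which(chars == "Z")
  if (length(z_pos) != 1) {
    abort("template must contain exactly one acceptor slot 'Z'")
  }
  x_pos <- which(chars == "X")
  names(residue_sets) <- as.character(names(residue_sets))
  missing <- setdiff(as.character(x_pos), names(residue_sets))
  if (length(missing) > 0) {
    abort(paste0("placeholder position(s) without residue set: ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(residue_sets), as.character(x_pos))
  if (length(extra) > 0) {
    abort(paste0("residue set(s) for non-placeholder position(s): ",
                 paste(extra, collapse = ", ")))
  }
  if (!all(acceptor_options %in% c("pS", "pT"))) {
    abort("acceptor_options must be a subset of c('pS', 'pT')")
  }
  structure(list(template = template, variant_positions = x_pos,
                 residue_sets = residue_sets,
                 acceptor_options = acceptor_options,
                 max_peptides = max_peptides),
            class = "library_spec")
}

#' Expand a library specification into peptides
#'
#' Enumerates every combination of variant residues and acceptor choice, in a
#' stable lexicographic order (variant positions left to right, acceptor
#' last), and assigns sequential `peptide_id`/`code_id` pairs so the
#' code-to-sequence mapping is 1:1. Each peptide is annotated with its
#' acceptor and +1 residue.
#'
#' @param spec a [library_spec()].
#' @return tibble: `peptide_id`, `code_id`, `sequence` (canonical notation),
#'   `phospho_position`, `acceptor`, `plus1_residue`.
#' @export
#' @examples
#' expand_library(library_spec("AZB"))
expand_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  chars <- strsplit(spec$template, "")[[1]]
  z_pos <- which(chars == "Z")
  x_pos <- spec$variant_positions
  option_list <- c(
    lapply(as.character(x_pos), function(p) spec$residue_sets[[p]]),
    list(spec$acceptor_options)
  )
  # expand.grid varies the first factor fastest; reverse both ways to get
  # lexicographic order with the leftmost position as the slowest digit.
  grid <- expand.grid(rev(option_list), stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  ord <- do.call(order, as.list(grid))
  grid <- grid[ord, , drop = FALSE]
  n_var <- length(x_pos)
  seqs <- vapply(seq_len(nrow(grid)), function(i) {
    s <- chars
    if (n_var > 0) s[x_pos] <- unlist(grid[i, seq_len(n_var)])
    s[z_pos] <- if (grid[i, n_var + 1] == "pS") "s" else "t"
    paste(s, collapse = "")
  }, character(1))
  if (anyDuplicated(seqs)) {
    dups <- unique(seqs[duplicated(seqs)])
    abort(paste0("duplicate expanded sequence(s): ",
                 paste(dups, collapse = ", ")))
  }
  if (is.finite(spec$max_peptides) && length(seqs) > spec$max_peptides) {
    seqs <- seqs[seq_len(spec$max_peptides)]
  }
  n <- length(seqs)
  lib <- tibble(
    peptide_id = sprintf("pep_%03d", seq_len(n)),
    code_id = sprintf("code_%03d", seq_len(n)),
    sequence = seqs
  )
  annotate_peptide(lib)
}

#' Annotate peptides with design attributes
#'
#' Adds (or refreshes) `phospho_position`, `acceptor` and `plus1_residue`
#' from the canonical sequence. The +1 residue is the residue immediately
#' C-terminal of the phospho position; a phosphoresidue at the C-terminus
#' gets the terminal marker `"*"`. Unphosphorylated sequences (negative
#' controls) get acceptor `"none"`.
#'
#' @param lib tibble with a `sequence` column in canonical notation, or a
#'   single sequence string.
#' @param primary_position for multiply phosphorylated sequences, the 1-based
#'   position to treat as the site of interest; without it such sequences
#'   are an error.
#' @return the input tibble with annotation columns.
#' @export
annotate_peptide <- function(lib, primary_position = NULL) {
  if (is.character(lib)) lib <- tibble(sequence = lib)
  ann <- lapply(lib$sequence, function(sq) {
    pp <- phospho_positions(sq)
    if (length(pp) == 0) {
      return(list(pos = NA_integer_, acceptor = "none",
                  plus1 = NA_character_))
    }
    if (length(pp) > 1) {
      if (is.null(primary_position)) {
        abort(paste0("sequence '", sq, "' has ", length(pp),
                     " phospho positions; designate a primary_position"))
      }
      if (!primary_position %in% pp) {
        abort("primary_position is not a phosphorylated position")
      }
      pp <- primary_position
    }
    res <- substr(sq, pp, pp)
    chars <- strsplit(sq, "")[[1]]
    plus1 <- if (pp < length(chars)) toupper(chars[pp + 1]) else "*"
    list(pos = pp, acceptor = paste0("p", toupper(res)), plus1 = plus1)
  })
  lib$phospho_position <- vapply(ann, function(a) as.integer(a$pos), integer(1))
  lib$acceptor <- vapply(ann, function(a) a$acceptor, character(1))
  lib$plus1_residue <- vapply(ann, function(a) a$plus1, character(1))
  lib
}

#' Default dephosphorylation panel specification
#'
#' A parameterised stand-in for a 94-peptide Ser/Thr panel built on the core
#' sequence LGAxxx(pS/pT)xLxxVSA: two variable positions immediately
#' N-terminal of the acceptor drawn from \{A, D, K, L\} (neutral, acidic,
#' basic, hydrophobic), both acceptors, and a +1 position drawn from
#' \{P, A, G\} so that proline-directed and non-proline-directed peptides are
#' both represented. The 96-way expansion is capped at `n` phosphopeptides
#' and a phosphate-free negative-control peptide is appended under the last
#' code.
#'
#' @param n number of phosphopeptides to keep (default 94).
#' @return tibble as from [expand_library()], with `n + 1` rows, the last
#'   being the negative control (acceptor `"none"`).
#' @export
dephos_panel <- function(n = 94) {
  spec <- library_spec(
    "LGAAXXZXLAAVSA",
    residue_sets = list(`5` = c("A", "D", "K", "L"),
                        `6` = c("A", "D", "K", "L"),
                        `8` = c("A", "G", "P")),
    acceptor_options = c("pS", "pT"),
    max_peptides = n
  )
  lib <- expand_library(spec)
  control <- annotate_peptide(tibble(
    peptide_id = "pep_ctrl",
    code_id = sprintf("code_%03d", n + 1),
    sequence = "LGAAAASALAAVSA"
  ))
  bind_rows(lib, control)
}

#' Read / write a peptide library file
#'
#' Libraries are TSV files with columns `peptide_id`, `code_id`, `sequence`
#' (any supported phospho notation on read; canonical on write) plus any
#' additional annotation columns. Reading re-derives the design annotations,
#' so a write-read round trip reproduces the table field for field.
#'
#' @param path file path.
#' @return `read_library()`: annotated library tibble.
#' @export
read_library <- function(path) {
  df <- validate_table(path, "library", quiet = TRUE)
  if (anyDuplicated(df$code_id)) {
    abort("code_id values must be unique within a library")
  }
  df$sequence <- normalize_phospho(df$sequence)
  annotate_peptide(df[c("peptide_id", "code_id", "sequence")])
}

#' @rdname read_library
#' @param lib annotated library tibble.
#' @export
write_library <- function(lib, path) {
  write_table(lib, path)
}
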