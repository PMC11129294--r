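# Elements the default featurization vocabulary covers. One-hot element
# encoding cannot generalize to elements unseen in training, so anything
# outside this set is rejected up front with a typed error.
QEQ_ELEMENTS <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

#' Parse a molecule record
#'
#' Reads a single molecule from a SMILES string, an SDF (V2000) record or a
#' MOL2 (TRIPOS) record. Every format is normalized through OpenBabel
#' (via \pkg{ChemmineOB}): hydrogens are made explicit, formal charges are
#' populated, and aromaticity is perceived. Multi-fragment records are
#' rejected — the total-charge constraint is defined per connected molecule.
#'
#' @param source A character scalar holding the record text (for SMILES, the
#'   SMILES string itself).
#' @param fmt One of `"smiles"`, `"sdf"`, `"mol2"`.
#' @param name Optional record label; defaults to the record's own title
#'   (SDF/MOL2) or the SMILES string.
#' @param vocabulary Character vector of allowed element symbols, or `NULL`
#'   to accept any element. Defaults to the featurization vocabulary: the
#'   one-hot element encoding makes out-of-vocabulary elements
#'   unrepresentable, so they are refused rather than silently mangled.
#'
#' @return A [molecule()].
#' @export
parse_molecule <- function(source, fmt = c("smiles", "sdf", "mol2"),
                           name = NULL, vocabulary = QEQ_ELEMENTS) {
  fmt <- match.arg(fmt)
  if (!is.character(source) || length(source) != 1L || !nzchar(trimws(source))) {
    qeq_abort("molecule source must be a non-empty character scalar", "parse_error")
  }
  sdf_text <- switch(fmt,
    smiles = {
      check_smiles_syntax(source)
      ob_convert("SMI", source)
    },
    sdf = ob_convert("SDF", source),
    mol2 = ob_convert("MOL2", source)
  )
  sdf <- read_sdf_text(sdf_text, source)
  if (length(sdf) != 1L) {
    qeq_abort(
      paste0("expected a single molecule record, found ", length(sdf)),
      "parse_error"
    )
  }
  if (is.null(name)) {
    title <- ChemmineR::header(sdf[[1]])[["Molecule_Name"]]
    name <- if (!is.null(title) && nzchar(trimws(title))) trimws(title)
            else if (fmt == "smiles") source else ""
  }
  sdf_to_molecule(sdf[[1]], name = name, vocabulary = vocabulary,
                  sdf_text = sdf_text)
}

# molfile part of an SDF record (up to and including M END)
molfile_part <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  end <- grep("^M  END", lines)
  if (!length(end)) return(NULL)
  paste(lines[seq_len(end[1])], collapse = "\n")
}

ob_convert <- function(from, source) {
  out <- tryCatch(
    ChemmineOB::convertFormat(
      from, "SDF", source,
      options = data.frame(names = "h", args = "")
    ),
    error = function(e) ""
  )
  if (!is.character(out) || !nzchar(trimws(out))) {
    qeq_abort(
      paste0("failed to parse ", from, " record: ", abbreviate_record(source)),
      "parse_error"
    )
  }
  out
}

abbreviate_record <- function(x) {
  x <- trimws(strsplit(x, "\n", fixed = TRUE)[[1]][1])
  if (nchar(x) > 60) paste0(substr(x, 1, 57), "...") else x
}

read_sdf_text <- function(text, source = text) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(text, tf)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(tf)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0L) {
    qeq_abort(
      paste0("failed to parse record: ", abbreviate_record(source)),
      "parse_error"
    )
  }
  sdf
}

# OpenBabel repairs many malformed SMILES silently, so the parse-error
# contract is enforced by a lexical screen: balanced brackets and branches,
# paired ring-closure labels, no dangling bond symbol.
check_smiles_syntax <- function(s) {
  bad <- function(why) {
    qeq_abort(paste0("malformed SMILES '", abbreviate_record(s), "': ", why),
              "parse_error")
  }
  chars <- strsplit(s, "")[[1]]
  allowed <- c(LETTERS, letters, as.character(0:9),
               "[", "]", "(", ")", "=", "#", "$", ":", "+", "-", "%", ".",
               "/", "\\", "@", "*", "~")
  if (!all(chars %in% allowed)) bad("illegal character")
  depth <- 0L; in_brk <- FALSE
  ring <- integer(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_brk) {
      if (ch == "]") in_brk <- FALSE
      if (ch == "[") bad("nested '['")
    } else if (ch == "[") {
      in_brk <- TRUE
    } else if (ch == "]") {
      bad("unmatched ']'")
    } else if (ch == "(") {
      depth <- depth + 1L
      if (i < n && chars[i + 1L] == ")") bad("empty branch '()'")
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) bad("unmatched ')'")
    } else if (grepl("[0-9]", ch)) {
      ring <- c(ring, as.integer(ch))
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        bad("'%' not followed by two digits")
      }
      ring <- c(ring, as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 2L
    }
    i <- i + 1L
  }
  if (in_brk) bad("unclosed '['")
  if (depth != 0L) bad("unclosed '('")
  if (any(table(ring) %% 2L != 0L)) bad("unpaired ring-closure label")
  if (grepl("[=#($:/\\\\+.-]$", s)) bad("dangling bond or branch")
  invisible(TRUE)
}

# V2000 legacy atom-block charge codes (column written by OpenBabel).
SDF_CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L,
                     `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)

sdf_to_molecule <- function(sdf, name = "", vocabulary = QEQ_ELEMENTS,
                            sdf_text = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  if (!is.null(vocabulary)) {
    unknown <- setdiff(unique(elements), vocabulary)
    if (length(unknown)) {
      qeq_abort(
        paste0(
          "element(s) ", paste(unknown, collapse = ", "),
          " outside the featurization vocabulary of record '", name, "'; ",
          "one-hot element encoding cannot represent unseen elements"
        ),
        "vocab_error"
      )
    }
  }
  charges <- rep(0L, length(elements))
  if ("C6" %in% colnames(ab)) {
    charges <- SDF_CHARGE_CODE[as.character(ab[, "C6"])]
    charges[is.na(charges)] <- 0L
  }
  bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    matrix(integer(0), ncol = 2)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  }
  aromatic <- perceive_aromatic(sdf, length(elements), bonds)
  mol <- molecule(elements, bonds, charges, name = name, aromatic = aromatic)
  # keep the normalized record so writers can reuse real bond orders
  if (!is.null(sdf_text)) mol$sdf <- molfile_part(sdf_text)
  mol
}

# Atoms belonging to a ring that ChemmineR's perception flags aromatic.
perceive_aromatic <- function(sdf, n, bonds) {
  aromatic <- rep(FALSE, n)
  if (nrow(bonds) < n) return(aromatic)  # acyclic: no aromatic ring possible
  rn <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, upper = 12, type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (is.null(rn) || !length(rn$RINGS)) return(aromatic)
  for (k in seq_along(rn$RINGS)) {
    if (isTRUE(rn$AROMATIC[[k]])) {
      idx <- as.integer(sub("^.*_", "", rn$RINGS[[k]]))
      aromatic[idx] <- TRUE
    }
  }
  aromatic
}

#' Read a multi-record molecule file
#'
#' Splits a SMILES (one record per line, optional whitespace-separated name),
#' SDF (records separated by `$$$$`) or MOL2 (records started by
#' `@<TRIPOS>MOLECULE`) file and parses each record independently. A record
#' that fails to parse does not abort the rest: failures are returned as
#' condition objects alongside the successes.
#'
#' @param path File path.
#' @param fmt One of `"smiles"`, `"sdf"`, `"mol2"`.
#' @param vocabulary Passed to [parse_molecule()].
#' @return A list with one element per record: either a [molecule()] or the
#'   error condition raised for it.
#' @export
read_molecules <- function(path, fmt = c("smiles", "sdf", "mol2"),
                           vocabulary = QEQ_ELEMENTS) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) {
    qeq_abort(paste0("input file not found: ", path), "io_error")
  }
  lines <- readLines(path, warn = FALSE)
  records <- switch(fmt,
    smiles = {
      lines <- lines[nzchar(trimws(lines))]
      lapply(lines, function(l) {
        parts <- strsplit(trimws(l), "[[:space:]]+")[[1]]
        list(source = parts[1],
             name = if (length(parts) > 1) paste(parts[-1], collapse = " ") else NULL)
      })
    },
    sdf = {
      idx <- cumsum(c(0L, head(grepl("^\\$\\$\\$\\$", lines), -1L)))
      chunks <- split(lines, idx)
      chunks <- Filter(function(ch) any(nzchar(trimws(ch))), chunks)
      lapply(chunks, function(ch) {
        list(source = paste(c(ch, "$$$$"), collapse = "\n"), name = NULL)
      })
    },
    mol2 = {
      starts <- grep("@<TRIPOS>MOLECULE", lines, fixed = TRUE)
      if (!length(starts)) qeq_abort("no @<TRIPOS>MOLECULE record in file", "parse_error")
      ends <- c(starts[-1] - 1L, length(lines))
      lapply(seq_along(starts), function(k) {
        list(source = paste(lines[starts[k]:ends[k]], collapse = "\n"), name = NULL)
      })
    }
  )
  unname(lapply(records, function(rec) {
    tryCatch(
      parse_molecule(rec$source, fmt, name = rec$name, vocabulary = vocabulary),
      qeqnet_error = function(e) e
    )
  }))
}
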