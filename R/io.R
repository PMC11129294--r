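# Build a connectivity-only V2000 molfile for a molecule. Parsed molecules
# carry the OpenBabel-normalized record (with real bond orders) in $sdf and
# use it instead; generated molecules are valence-complete with explicit
# hydrogens, so single-bond connectivity plus M CHG lines round-trips
# faithfully. Coordinates are zero: the whole method is geometry-agnostic.
molfile_text <- function(mol) {
  if (!is.null(mol$sdf)) return(mol$sdf)
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  lines <- c(
    mol$name, " qeqnet", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, mol$elements)
  )
  if (nb > 0) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              mol$bonds[, 1], mol$bonds[, 2], 1L))
  }
  chg <- which(mol$formal_charges != 0L)
  if (length(chg)) {
    for (start in seq(1, length(chg), by = 8)) {
      grp <- chg[start:min(start + 7, length(chg))]
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, mol$formal_charges[grp]), collapse = "")
      ))
    }
  }
  paste(c(lines, "M  END"), collapse = "\n")
}

# Round to the writer's fixed precision while preserving the exact charge
# sum: the post-rounding residual is added to the largest-|q| atom, so the
# written values still sum to Q exactly (Q has an exact 6-decimal form).
round_preserve_sum <- function(charges, Q, digits = 6L) {
  q <- round(charges, digits)
  resid <- round(Q - sum(q), digits)
  if (resid != 0) {
    k <- which.max(abs(charges))
    q[k] <- q[k] + resid
  }
  q
}

#' Serialize a molecule with its partial charges
#'
#' Writes one annotated record. SDF: the molecule's V2000 block followed by
#' the charges in a named data tag, one value per atom in input atom order,
#' fixed 6-decimal precision. MOL2: a TRIPOS record with the charges in the
#' per-atom charge column and the charge-type line set to `USER_CHARGES`
#' (this package's documented label for model-assigned charges). In both
#' formats the written values are rounding-repaired so their sum equals the
#' molecule's total formal charge exactly.
#'
#' @param mol A [molecule()].
#' @param charges Numeric vector, one charge per atom.
#' @param fmt `"sdf"` or `"mol2"`.
#' @param tag SDF data-tag name for the charges.
#' @return A character scalar holding the serialized record.
#' @export
write_charges <- function(mol, charges, fmt = c("sdf", "mol2"),
                          tag = "PARTIAL_CHARGES") {
  fmt <- tryCatch(match.arg(fmt), error = function(e) {
    qeq_abort(paste0("unsupported output format: ", fmt[1]), "io_error")
  })
  stopifnot(inherits(mol, "qeq_mol"))
  if (length(charges) != n_atoms(mol)) {
    qeq_abort("one charge per atom is required", "dim_error")
  }
  q <- round_preserve_sum(charges, total_formal_charge(mol))
  if (fmt == "sdf") {
    paste(c(
      molfile_text(mol),
      paste0("> <", tag, ">"),
      sprintf("%.6f", q),
      "", "$$$$"
    ), collapse = "\n")
  } else {
    n <- n_atoms(mol)
    nb <- nrow(mol$bonds)
    atom_lines <- sprintf(
      "%7d %-4s %9.4f %9.4f %9.4f %-5s %3d %-8s %9.6f",
      seq_len(n), paste0(mol$elements, seq_len(n)), 0, 0, 0,
      mol$elements, 1L, "MOL1", q
    )
    bond_lines <- if (nb > 0) {
      sprintf("%6d %5d %5d %4s", seq_len(nb), mol$bonds[, 1], mol$bonds[, 2], "1")
    }
    paste(c(
      "@<TRIPOS>MOLECULE",
      if (nzchar(mol$name)) mol$name else "*****",
      sprintf(" %d %d 0 0 0", n, nb),
      "SMALL",
      "USER_CHARGES",
      "",
      "@<TRIPOS>ATOM",
      atom_lines,
      "@<TRIPOS>BOND",
      bond_lines
    ), collapse = "\n")
  }
}

#' Read per-atom charges back from an annotated file
#'
#' Parses the charge annotations written by [write_charges()]: the named SDF
#' data tag, or the MOL2 per-atom charge column.
#'
#' @param path File path (may hold several records).
#' @param fmt `"sdf"` or `"mol2"`.
#' @param tag SDF data-tag name.
#' @return A list with one numeric charge vector per record.
#' @export
read_charges <- function(path, fmt = c("sdf", "mol2"), tag = "PARTIAL_CHARGES") {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) qeq_abort(paste0("file not found: ", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  if (fmt == "sdf") {
    rec_id <- cumsum(c(0L, head(grepl("^\\$\\$\\$\\$", lines), -1L)))
    recs <- split(lines, rec_id)
    recs <- Filter(function(r) any(nzchar(trimws(r))), recs)
    recs <- unname(recs)
    lapply(recs, function(r) {
      start <- grep(paste0("^>\\s*<", tag, ">"), r)
      if (!length(start)) {
        qeq_abort(paste0("no <", tag, "> data tag in record"), "io_error")
      }
      vals <- character(0)
      i <- start[1] + 1L
      while (i <= length(r) && nzchar(trimws(r[i])) && !grepl("^[>$]", r[i])) {
        vals <- c(vals, trimws(r[i]))
        i <- i + 1L
      }
      as.numeric(vals)
    })
  } else {
    starts <- grep("@<TRIPOS>MOLECULE", lines, fixed = TRUE)
    if (!length(starts)) qeq_abort("no MOL2 record in file", "io_error")
    ends <- c(starts[-1] - 1L, length(lines))
    lapply(seq_along(starts), function(k) {
      r <- lines[starts[k]:ends[k]]
      a0 <- grep("@<TRIPOS>ATOM", r, fixed = TRUE)[1]
      a1 <- grep("@<TRIPOS>", r, fixed = TRUE)
      a1 <- min(c(a1[a1 > a0], length(r) + 1L))
      atom_lines <- r[(a0 + 1L):(a1 - 1L)]
      atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
      vapply(strsplit(trimws(atom_lines), "[[:space:]]+"), function(f) {
        as.numeric(f[[length(f)]])
      }, numeric(1))
    })
  }
}

write_lines_atomic <- function(text, path) {
  tmp <- paste0(path, ".tmp")
  writeLines(text, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a labelled dataset as SDF
#'
#' One SDF record per molecule with the reference charges in a
#' `REFERENCE_CHARGES` data tag (and the split label in a `SPLIT` tag when
#' assigned) — the dialect [read_charge_dataset()] reads back.
#'
#' @param dataset A [charge_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_charge_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "qeq_dataset"))
  recs <- vapply(seq_len(nrow(dataset)), function(i) {
    mol <- dataset$molecule[[i]]
    rec <- write_charges(mol, dataset$ref[[i]], "sdf", tag = "REFERENCE_CHARGES")
    if (!is.na(dataset$split[i])) {
      rec <- sub("\n\\$\\$\\$\\$$",
                 paste0("\n> <SPLIT>\n", dataset$split[i], "\n\n$$$$"), rec)
    }
    rec
  }, character(1))
  write_lines_atomic(paste(recs, collapse = "\n"), path)
}

#' Read a labelled dataset from SDF
#'
#' @param path File written by [write_charge_dataset()] (or any SDF whose
#'   records carry a `REFERENCE_CHARGES` tag).
#' @return A [charge_dataset()] (with `split` labels if present).
#' @export
read_charge_dataset <- function(path) {
  mols <- read_molecules(path, "sdf")
  bad <- vapply(mols, inherits, logical(1), "condition")
  if (any(bad)) {
    qeq_abort(paste0("record ", which(bad)[1], " failed to parse: ",
                     conditionMessage(mols[[which(bad)[1]]])), "parse_error")
  }
  charges <- read_charges(path, "sdf", tag = "REFERENCE_CHARGES")
  ds <- charge_dataset(mols, charges)
  lines <- readLines(path, warn = FALSE)
  rec_id <- cumsum(c(0L, head(grepl("^\\$\\$\\$\\$", lines), -1L)))
  recs <- Filter(function(r) any(nzchar(trimws(r))), split(lines, rec_id))
  splits <- vapply(recs, function(r) {
    i <- grep("^>\\s*<SPLIT>", r)
    if (length(i) && i[1] < length(r)) trimws(r[i[1] + 1L]) else NA_character_
  }, character(1))
  ds$split <- unname(splits)
  ds
}
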