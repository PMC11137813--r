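#' Read and write tabulated potential curves
#'
#' Curves travel as headered tab-delimited text: `#`-prefixed metadata
#' lines carrying the provenance label, units and force convention,
#' followed by a header row and the `r` / `U` / `F` columns.
#'
#' @param curve A [potential_curve()].
#' @param path File path.
#' @return `write_curve` returns `path` invisibly; `read_curve` the
#'   restored `potential_curve`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "potential_curve"))
  cols <- intersect(c("r", "U", "F"), names(curve))
  units <- c(r = "Angstrom", U = "kcal/mol", F = "kcal/mol/Angstrom")
  meta <- c(sprintf("# label: %s", curve_label(curve)),
            sprintf("# f_method: %s", curve_f_method(curve)),
            sprintf("# units: %s", paste(sprintf("%s=%s", cols, units[cols]),
                                         collapse = " ")))
  body <- vapply(seq_len(nrow(curve)), function(i) {
    paste(vapply(cols, function(cn) sprintf("%.10g", curve[[cn]][i]), character(1)),
          collapse = "\t")
  }, character(1))
  writeLines(c(meta, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  label <- sub("^# label: ", "", grep("^# label:", meta, value = TRUE))
  fm <- sub("^# f_method: ", "", grep("^# f_method:", meta, value = TRUE))
  units_line <- grep("^# units:", meta, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L) stop("curve file has no data rows: ", path, call. = FALSE)
  header <- strsplit(body[1], "\t")[[1]]
  if (!"r" %in% header)
    stop("curve file missing `r` column (line ", length(meta) + 1, ")", call. = FALSE)
  if (length(units_line) == 1L) {
    want <- c(r = "r=Angstrom", U = "U=kcal/mol", F = "F=kcal/mol/Angstrom")
    for (cn in intersect(names(want), header)) {
      if (!grepl(want[[cn]], units_line, fixed = TRUE))
        stop("unit mismatch in curve header for column `", cn, "`", call. = FALSE)
    }
  }
  vals <- utils::read.table(text = paste(body[-1], collapse = "\n"),
                            sep = "\t", col.names = header)
  out <- tibble::as_tibble(vals)
  new_potential_curve(out, label = if (length(label)) label else "curve",
                      f_method = if (length(fm) && fm != "NA") fm else NA_character_)
}

#' Export pair parameters as an NBFIX-style block
#'
#' One line per atom-type pair, well depth as printed (negative) and the
#' length either as the sigma-form value (`"as-printed"`) or converted to
#' the CHARMM R_min convention (`R_min = 2^{1/6} sigma`). The header
#' comment records which convention the file uses, and [read_nbfix()]
#' honours it on the way back in.
#'
#' @param params Named list of [lj_pair()]s (names are the pair labels,
#'   e.g. `"FE CCO"`); a [coordination_params()] set works directly.
#' @param path File path or `""` for stdout.
#' @param convention `"as-printed"` (sigma form) or `"rmin"`.
#' @return `write_nbfix` returns the lines invisibly; `read_nbfix` a
#'   named list of `lj_pair`s.
#' @export
write_nbfix <- function(params, path = "", convention = c("as-printed", "rmin")) {
  convention <- match.arg(convention)
  labels <- names(params)
  if (is.null(labels) || anyDuplicated(labels))
    stop("pair labels must be present and unique", call. = FALSE)
  lines <- c("* pair-specific LJ overrides (NBFIX)",
             sprintf("* length convention: %s", convention),
             "NBFIX")
  for (k in seq_along(params)) {
    p <- params[[k]]
    len <- if (convention == "rmin") lj_sigma_internal(p) * 2^(1/6)
           else lj_sigma_internal(p)
    lines <- c(lines, sprintf("%-12s %10.4f %10.4f",
                              toupper(gsub("[^A-Za-z0-9 ]", " ", labels[k])),
                              -abs(p$epsilon), len))
  }
  lines <- c(lines, "END")
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}

#' @rdname write_nbfix
#' @export
read_nbfix <- function(path) {
  lines <- readLines(path)
  conv_line <- grep("^\\* length convention:", lines, value = TRUE)
  conv <- if (length(conv_line) && grepl("rmin", conv_line)) "rmin" else "as-printed"
  start <- match("NBFIX", lines)
  if (is.na(start)) stop("no NBFIX block in ", path, call. = FALSE)
  body <- lines[seq(start + 1, length(lines))]
  body <- body[!grepl("^(END|\\*|!|$)", body)]
  out <- list()
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) < 3L)
      stop("malformed NBFIX line ", start + i, ": ", body[i], call. = FALSE)
    nt <- length(tok)
    eps <- as.numeric(tok[nt - 1]); len <- as.numeric(tok[nt])
    if (any(is.na(c(eps, len))))
      stop("malformed NBFIX line ", start + i, ": ", body[i], call. = FALSE)
    lab <- paste(tok[seq_len(nt - 2)], collapse = " ")
    out[[lab]] <- lj_pair(eps, len,
                          convention = if (conv == "rmin") "rmin" else "sigma")
  }
  out
}

# fixed-width PDB ATOM record
pdb_atom_line <- function(serial, name, resname, resseq, xyz, element) {
  sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, substr(name, 1, 4), substr(resname, 1, 4), resseq,
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}

PDB_SITE_NAMES <- c(fe = "FE", n_heme = "N", c_ring = "C", n_im = "NIM",
                    c_co = "C", o_co = "OC", o2 = "O2", o1 = "O1")
PDB_RESNAMES <- c(fe = "HEM", n_heme = "HEM", c_ring = "HEM", n_im = "IMD",
                  c_co = "CMO", o_co = "CMO", o2 = "OXY", o1 = "OXY")

#' Write / read a reduced complex as PDB
#'
#' Coordinates travel as standard fixed-width ATOM records (Angstrom,
#' as the PDB convention requires); site roles map to atom/residue names
#' (`FE`/`HEM` for the iron, `N` for heme nitrogens, `NIM`/`IMD` for the
#' imidazole anchor, `C`,`OC`/`CMO` for CO, `O2`,`O1`/`OXY` for the two
#' oxygen sites). A trajectory writes one MODEL block per frame.
#'
#' @param complex A [build_complex()] result.
#' @param path File path.
#' @return `write_pdb_complex` returns `path` invisibly;
#'   `read_pdb_complex` a `reduced_complex`.
#' @export
write_pdb_complex <- function(complex, path) {
  stopifnot(inherits(complex, "reduced_complex"))
  pos <- complex_positions(complex)
  lines <- vapply(seq_len(nrow(complex)), function(i) {
    role <- complex$role[i]
    nm <- if (role %in% c("n_heme", "c_ring")) toupper(complex$site[i])
          else PDB_SITE_NAMES[[role]]
    pdb_atom_line(i, nm, PDB_RESNAMES[[role]], 1L, pos[i, ], complex$element[i])
  }, character(1))
  writeLines(c(sprintf("REMARK   ligand %s", attr(complex, "ligand")), lines, "END"),
             path)
  invisible(path)
}

#' @rdname write_pdb_complex
#' @export
read_pdb_complex <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  names_up <- toupper(trimws(at$elety))
  if (!"FE" %in% names_up)
    stop("PDB is missing the required FE record", call. = FALSE)
  role_of <- function(nm) {
    if (nm == "FE") "fe" else if (grepl("^N[1-4]$", nm)) "n_heme"
    else if (grepl("^(CA[1-8]|CM[1-4])$", nm)) "c_ring"
    else if (nm == "NIM") "n_im" else if (nm == "C") "c_co"
    else if (nm == "OC") "o_co" else if (nm == "O2") "o2"
    else if (nm == "O1") "o1" else NA_character_
  }
  roles <- vapply(names_up, role_of, character(1))
  if (any(is.na(roles)))
    stop("unrecognized atom name(s): ",
         paste(unique(names_up[is.na(roles)]), collapse = ", "), call. = FALSE)
  ligand <- if (all(c("c_co", "o2") %in% roles)) "CO+O2"
            else if ("c_co" %in% roles) "CO" else "O2"
  cx <- build_complex(ligand)
  ord <- match(cx$role, roles)
  # ring roles repeat; match those by site name
  for (k in which(cx$role %in% c("n_heme", "c_ring")))
    ord[k] <- which(names_up == toupper(cx$site[k]))
  if (any(is.na(ord))) stop("PDB does not contain the reduced-complex sites", call. = FALSE)
  pos <- cbind(at$x, at$y, at$z)[ord, , drop = FALSE]
  with_positions(cx, pos)
}

#' Write a trajectory as a multi-MODEL PDB
#'
#' @param run An `md_run` with recorded positions.
#' @param path File path.
#' @export
write_pdb_trajectory <- function(run, path) {
  stopifnot(inherits(run, "md_run"))
  if (is.null(run$positions)) stop("run has no recorded positions", call. = FALSE)
  cx <- run$complex
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   ligand %s, %d frames", attr(cx, "ligand"),
                     nrow(run$positions)), con)
  for (k in seq_len(nrow(run$positions))) {
    p <- matrix(run$positions[k, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(vapply(seq_len(nrow(cx)), function(i) {
      role <- cx$role[i]
      nm <- if (role == "n_heme") toupper(cx$site[i]) else PDB_SITE_NAMES[[role]]
      pdb_atom_line(i, nm, PDB_RESNAMES[[role]], 1L, p[i, ], cx$element[i])
    }, character(1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a JSON run configuration
#'
#' Validates the fields shared by the pipeline stages: restraint
#' stiffnesses must be non-negative, durations/rates positive, the
#' ligand one of the supported choices, and any `geometry` entries are
#' checked by [complex_geometry()].
#'
#' @param path JSON file.
#' @return A named list with a `geometry` element replaced by a
#'   [complex_geometry()].
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  chk <- function(cond, msg) if (!cond) stop("config error: ", msg, call. = FALSE)
  if (!is.null(cfg$o2_kappa))
    chk(all(cfg$o2_kappa >= 0), "`o2_kappa` must be non-negative")
  for (f in c("duration_ps", "relax_ps", "rate", "kappa_pull", "hill_height",
              "hill_sigma", "temperature", "n_rep", "n_total"))
    if (!is.null(cfg[[f]])) chk(all(cfg[[f]] > 0), paste0("`", f, "` must be positive"))
  if (!is.null(cfg$bias_factor))
    chk(cfg$bias_factor > 1, "`bias_factor` must exceed 1")
  if (!is.null(cfg$ligand))
    chk(cfg$ligand %in% c("CO", "O2", "CO+O2"), "unknown `ligand`")
  if (!is.null(cfg$geometry)) cfg$geometry <- do.call(complex_geometry, cfg$geometry)
  cfg
}
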