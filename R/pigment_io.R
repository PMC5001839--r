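#' Write a pigment table to TSV
#'
#' Serializes the pigment coordinates of a vesicle model in the package's
#' TSV dialect (tab-separated, header row, Angstrom, 6 decimal places):
#' `cluster_id, cluster_type, pigment_class, ring_index, mg_x..mg_z,
#' nb_x..nb_z, nd_x..nd_z`. Derived columns (dipoles, site energies) are not
#' written; they are recomputed on read.
#'
#' @param vesicle a `vesicle_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pigment_table <- function(vesicle, path) {
  p <- vesicle$pigments
  cols <- c("cluster_id", "cluster_type", "pigment_class", "ring_index",
            "mg_x", "mg_y", "mg_z", "nb_x", "nb_y", "nb_z",
            "nd_x", "nd_y", "nd_z")
  out <- p[, cols]
  for (cc in cols[5:13]) out[[cc]] <- sprintf("%.6f", out[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

pigment_classes <- c("B850_alpha", "B850_beta", "B800", "B875",
                     "RC_special", "RC_accessory")

#' Read a pigment table into a vesicle model
#'
#' Reads either the package TSV dialect (see [write_pigment_table()]) or a
#' PDB-style file with `BCL` residues carrying `MG`, `NB` and `ND` atoms
#' (cluster assignment by chain identifier; pigment classes inferred from
#' cluster size: 4 BChls = RC, 18 = LH2 B850, 28 = LH1 B875, 9 = B800).
#' Transition dipoles are recomputed from the NB/ND atoms and site energies
#' are reassigned from the constants registry, so a written-then-read model
#' reproduces the original up to coordinate round-off.
#'
#' @param path input file; format chosen by extension (`.pdb` for PDB-style,
#'   TSV otherwise) or via `format`.
#' @param format `"tsv"`, `"pdb"` or `"auto"`.
#' @param params an [exciton_params()] registry for site energies.
#' @return A `vesicle_model`. Composition counts beyond what the pigment
#'   table implies (bc1 dimers, ATP synthases) are zero: pigment-free
#'   complexes do not appear in coordinate files.
#' @export
read_pigment_table <- function(path, format = c("auto", "tsv", "pdb"),
                               params = exciton_params()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "tsv"
  pigments <- if (format == "pdb") parse_pdb_pigments(path)
              else parse_tsv_pigments(path)
  vesicle_from_pigments(pigments, params = params)
}

parse_tsv_pigments <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("cluster_id", "cluster_type", "pigment_class", "ring_index",
            "mg_x", "mg_y", "mg_z", "nb_x", "nb_y", "nb_z",
            "nd_x", "nd_y", "nd_z")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0)
    stop("pigment table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  # line numbers in the file: header is line 1
  line_of <- function(i) i + 1L
  bad_class <- which(!(tab$pigment_class %in% pigment_classes))
  if (length(bad_class) > 0)
    stop("pigment table ", path, ", line ", line_of(bad_class[1]),
         ": unknown pigment_class '", tab$pigment_class[bad_class[1]], "'")
  num_cols <- need[5:13]
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop("pigment table ", path, ", line ", line_of(bad[1]),
           ": non-numeric or missing ", cc)
    tab[[cc]] <- v
  }
  key <- paste(tab$cluster_id, tab$pigment_class %in% c("B800"),
               tab$ring_index)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop("pigment table ", path, ", line ", line_of(dup[1]),
         ": duplicate (cluster_id, ring_index) pair")
  tab[, need]
}

parse_pdb_pigments <- function(path) {
  lines <- readLines(path)
  sel <- grepl("^(ATOM|HETATM)", lines) &
    toupper(substr(lines, 18, 20)) == "BCL"
  idx <- which(sel)
  if (length(idx) == 0)
    stop("PDB file ", path, ": no BCL residues found")
  rec <- lines[idx]
  atom <- trimws(substr(rec, 13, 16))
  chain <- substr(rec, 22, 22)
  resseq <- suppressWarnings(as.integer(substr(rec, 23, 26)))
  x <- suppressWarnings(as.numeric(substr(rec, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(rec, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(rec, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resseq))
  if (length(bad) > 0)
    stop("PDB file ", path, ", line ", idx[bad[1]],
         ": malformed coordinate record")
  keep <- atom %in% c("MG", "NB", "ND")
  atom <- atom[keep]; chain <- chain[keep]; resseq <- resseq[keep]
  x <- x[keep]; y <- y[keep]; z <- z[keep]; lineno <- idx[keep]

  out <- list()
  for (ch in unique(chain)) {
    in_ch <- chain == ch
    residues <- sort(unique(resseq[in_ch]))
    n <- length(residues)
    classes <- switch(as.character(n),
                      "4" = c("RC_special", "RC_special",
                              "RC_accessory", "RC_accessory"),
                      "18" = rep_len(c("B850_alpha", "B850_beta"), 18),
                      "28" = rep("B875", 28),
                      "9" = rep("B800", 9),
                      stop("PDB file ", path, ": chain ", ch, " has ", n,
                           " BCL residues; cannot infer pigment classes ",
                           "(expected 4, 9, 18 or 28)"))
    ctype <- switch(as.character(n), "4" = "RC", "18" = "LH2",
                    "28" = "LH1", "9" = "LH2")
    rows <- lapply(seq_along(residues), function(i) {
      rr <- residues[i]
      pick <- function(a) {
        j <- which(in_ch & resseq == rr & atom == a)
        if (length(j) != 1)
          stop("PDB file ", path, ": residue ", rr, " chain ", ch,
               " is missing atom ", a, " (or has duplicates)")
        c(x[j], y[j], z[j])
      }
      mg <- pick("MG"); nb <- pick("NB"); nd <- pick("ND")
      data.frame(cluster_id = paste0("chain_", ch),
                 cluster_type = ctype, pigment_class = classes[i],
                 ring_index = i,
                 mg_x = mg[1], mg_y = mg[2], mg_z = mg[3],
                 nb_x = nb[1], nb_y = nb[2], nb_z = nb[3],
                 nd_x = nd[1], nd_y = nd[2], nd_z = nd[3],
                 stringsAsFactors = FALSE)
    })
    out[[ch]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

# Assemble a vesicle_model from a raw pigment table (counts inferred).
vesicle_from_pigments <- function(pigments, params = exciton_params(),
                                  config = geometry_config()) {
  rownames(pigments) <- NULL
  net <- pigments[pigments$pigment_class != "B800", ]
  rc_ids <- unique(net$cluster_id[net$cluster_type == "RC"])
  for (cid in rc_ids) {
    n <- sum(net$cluster_id == cid)
    if (n != 4)
      stop("RC cluster ", cid, " has ", n, " pigments; RC requires 4")
  }
  lh_ids <- unique(net$cluster_id[net$cluster_type %in% c("LH2", "LH1")])
  for (cid in lh_ids) {
    n <- sum(net$cluster_id == cid)
    if (n > 1 && n %% 2 != 0)
      stop("cluster ", cid, " has an odd pigment count (", n,
           "); alternating ring structure requires an even count")
  }
  n_lh2 <- length(unique(net$cluster_id[net$cluster_type == "LH2"]))
  n_rc <- length(rc_ids)
  composition <- list(n_lh2 = n_lh2,
                      n_l_dimers = n_rc / 2,
                      n_l_monomers = 0L,
                      n_bc1_dimers = 0L,
                      n_atp_synthase = 0L)
  finalize_vesicle(pigments, composition, config, proteins = NULL,
                   params = params)
}
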