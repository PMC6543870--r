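# Atom-typing dictionaries for the 20 standard amino acids.
#
# Typing drives the seven interaction flags: hydrogen-bond donors/acceptors,
# apolar (hydrophobic) carbons, formal-charge centers at pH 7, and aromatic
# ring systems. Side-chain carbons bonded to N/O/S-H are excluded from the
# apolar set; methionine CG/CE are kept (conventionally hydrophobic).

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

PROTEIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH",
  TRP = "NE1")

PROTEIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

PROTEIN_CATIONS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
PROTEIN_ANIONS  <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

PROTEIN_APOLAR <- list(
  ALA = "CB", ARG = c("CB", "CG"), ASN = "CB", ASP = "CB", CYS = "CB",
  GLN = c("CB", "CG"), GLU = c("CB", "CG"), HIS = "CB",
  ILE = c("CB", "CG1", "CG2", "CD1"), LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD"), MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG"), THR = "CG2",
  TRP = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  VAL = c("CB", "CG1", "CG2"))

PROTEIN_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))

ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    F = 18.998, P = 30.974, S = 32.06, CL = 35.45,
                    BR = 79.904, I = 126.904)

# Infer element from a PDB atom name when no element column is available.
element_from_name <- function(atom) {
  a <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", atom)))
  two <- substr(a, 1, 2)
  out <- ifelse(two %in% c("CL", "BR"), two, substr(a, 1, 1))
  out[!out %in% names(ELEMENT_MASSES)] <- "C"
  out
}

# Build typing columns for protein atoms from the residue dictionaries.
# Returns a data.frame aligned with `atom`/`resid` vectors; ring_id is a
# per-residue-local ring index combined with resno to be globally unique.
type_protein_atoms <- function(atom, resid, resno) {
  n <- length(atom)
  donor <- acceptor <- apolar <- aromatic <- logical(n)
  charge <- numeric(n)
  ring_id <- rep(NA_character_, n)
  backbone_donor <- atom == "N" & resid != "PRO"
  backbone_acceptor <- atom %in% c("O", "OXT")
  for (i in seq_len(n)) {
    rs <- resid[i]; at <- atom[i]
    donor[i] <- backbone_donor[i] || at %in% PROTEIN_DONORS[[rs]]
    acceptor[i] <- backbone_acceptor[i] || at %in% PROTEIN_ACCEPTORS[[rs]]
    apolar[i] <- at %in% PROTEIN_APOLAR[[rs]]
    if (at %in% PROTEIN_CATIONS[[rs]]) charge[i] <- 1
    if (at %in% PROTEIN_ANIONS[[rs]]) charge[i] <- -1
    rings <- PROTEIN_RINGS[[rs]]
    if (!is.null(rings)) {
      for (k in seq_along(rings)) {
        if (at %in% rings[[k]]) {
          aromatic[i] <- TRUE
          ring_id[i] <- paste0("P", resno[i], ".", k)
          break
        }
      }
    }
  }
  data.frame(donor = donor, acceptor = acceptor, apolar = apolar,
             aromatic = aromatic, charge = charge, ring_id = ring_id,
             stringsAsFactors = FALSE)
}

#' Default ligand atom typing from element identity
#'
#' Used when no explicit ligand typing table is supplied: nitrogen and oxygen
#' atoms are treated as both hydrogen-bond donors and acceptors, carbons as
#' apolar, and no formal charges or aromatic rings are assigned. Synthetic
#' fixtures and real ligands should supply an explicit table via
#' [read_trajectory()]'s `ligand_types` argument instead.
#'
#' @param atom character vector of atom names.
#' @param element character vector of element symbols.
#' @return a ligand typing data.frame (one row per atom).
#' @export
default_ligand_types <- function(atom, element = element_from_name(atom)) {
  element <- toupper(element)
  data.frame(atom = atom, element = element,
             charge = 0,
             aromatic = FALSE,
             donor = element %in% c("N", "O"),
             acceptor = element %in% c("N", "O"),
             apolar = element == "C",
             ring_id = NA_character_,
             stringsAsFactors = FALSE)
}

validate_ligand_types <- function(lt) {
  req <- c("atom", "charge", "aromatic", "donor", "acceptor", "apolar")
  miss <- setdiff(req, names(lt))
  if (length(miss))
    stopf("ligand typing table lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(lt$ring_id)) lt$ring_id <- NA_character_
  lt$ring_id <- as.character(lt$ring_id)
  lt$ring_id[!is.na(lt$ring_id)] <- paste0("L", lt$ring_id[!is.na(lt$ring_id)])
  if (is.null(lt$element)) lt$element <- element_from_name(lt$atom)
  lt
}
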