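# Physicochemical profiling: molecular weight, net charge,
# isoelectric point and CXC X-residue polarity.

# Average residue (amino-acid minus water) masses in daltons, and the
# corresponding monoisotopic values.
AA_MASS_AVERAGE <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
AA_MASS_MONO <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
WATER_AVERAGE <- 18.01524
WATER_MONO <- 18.010565

#' Protein molecular weight
#'
#' Sum of residue masses plus one water.
#'
#' @param seq residue string or one-row record data.frame; must not
#'   contain the unknown residue `X`.
#' @param mode `"average"` (default; whole-protein dalton scale) or
#'   `"monoisotopic"`.
#' @param masses optional named residue-mass override vector.
#' @return molecular weight in daltons.
#' @export
#' @examples
#' molecular_weight("G")  # 75.07
molecular_weight <- function(seq, mode = c("average", "monoisotopic"),
                             masses = NULL) {
  mode <- match.arg(mode)
  s <- residue_string(seq)
  if (!nzchar(s)) stop("empty residue string", call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  xpos <- which(chars == "X")
  if (length(xpos))
    stop(sprintf("unknown residue 'X' at position(s) %s",
                 paste(xpos, collapse = ", ")), call. = FALSE)
  tab <- masses %||% if (mode == "average") AA_MASS_AVERAGE else AA_MASS_MONO
  water <- if (mode == "average") WATER_AVERAGE else WATER_MONO
  bad <- setdiff(unique(chars), names(tab))
  if (length(bad))
    stop(sprintf("no mass for residue(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  sum(tab[chars]) + water
}

#' Default pKa table (Bjellqvist-style)
#'
#' Side-chain pKa values for D, E, C, Y, H, K, R plus the alpha-amino
#' (`Nterm`) and alpha-carboxyl (`Cterm`) groups, as used by the classic
#' ExPASy-style pI computation.  Any entry may be overridden; setting an
#' entry to `NA` removes that group from the charge model.
#'
#' @return named numeric vector.
#' @export
default_pka <- function() {
  c(Nterm = 7.5, Cterm = 3.55,
    D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
    H = 5.98, K = 10.0, R = 12.0)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum: positive contributions from the
#' N-terminus, H, K and R; negative from the C-terminus, D, E, C and Y.
#' Unknown residues (`X`) carry no charge.
#'
#' @param seq residue string or one-row record data.frame.
#' @param pH pH value(s) in `[0, 14]` (vectorised).
#' @param pka pKa table (see [default_pka()]).
#' @return net charge in elementary units, one value per `pH`.
#' @export
net_charge <- function(seq, pH = 7, pka = default_pka()) {
  s <- residue_string(seq)
  stopifnot(all(pH >= 0 & pH <= 14))
  chars <- strsplit(s, "")[[1]]
  counts <- table(factor(chars, levels = AA20))
  pos_groups <- c(Nterm = 1, H = unname(counts["H"]), K = unname(counts["K"]),
                  R = unname(counts["R"]))
  neg_groups <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
                  C = unname(counts["C"]), Y = unname(counts["Y"]))
  vapply(pH, function(p) {
    pos <- sum(vapply(names(pos_groups), function(g) {
      k <- pka[g]
      if (is.na(k)) return(0)
      pos_groups[g] / (1 + 10^(p - k))
    }, 0))
    neg <- sum(vapply(names(neg_groups), function(g) {
      k <- pka[g]
      if (is.na(k)) return(0)
      neg_groups[g] / (1 + 10^(k - p))
    }, 0))
    pos - neg
  }, 0)
}

#' Isoelectric point
#'
#' pH at which the net charge is zero, found by bisection on `[0, 14]`
#' to `|charge| < tol`.  A sequence whose charge does not change sign on
#' the interval (no titratable positive or negative groups under the
#' given pKa table) returns the boundary value with attribute
#' `boundary = TRUE`.
#'
#' @inheritParams net_charge
#' @param tol charge tolerance (default 1e-4).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka = default_pka(), tol = 1e-4) {
  f <- function(p) net_charge(seq, p, pka)
  lo <- 0; hi <- 14
  flo <- f(lo); fhi <- f(hi)
  if (flo <= 0) return(structure(lo, boundary = TRUE))
  if (fhi >= 0) return(structure(hi, boundary = TRUE))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Polarity partition of the 20 residues plus X.  The CXC X residue is
# hydrophilic in classical nsLTP1-like proteins (e.g. asparagine) and
# hydrophobic in nsLTP2-like ones (e.g. leucine, phenylalanine); G, P, C
# and the unknown X are left unassigned ("other").
POLARITY_HYDROPHILIC <- c("S", "T", "N", "Q", "D", "E", "K", "R", "H")
POLARITY_HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "Y")
POLARITY_OTHER <- c("G", "P", "C", "X")

#' Polarity class of the CXC X residue
#'
#' @param x a single residue character, or a one-row motif data.frame
#'   from [find_cys_motifs()] (its `cxc_x` column is used).
#' @return `"hydrophilic"`, `"hydrophobic"` or `"other"`.
#' @export
cxc_polarity <- function(x) {
  if (is.data.frame(x)) { stopifnot(nrow(x) == 1L); x <- x$cxc_x }
  stopifnot(is.character(x), length(x) == 1L, nchar(x) == 1L)
  x <- toupper(x)
  if (x %in% POLARITY_HYDROPHILIC) "hydrophilic"
  else if (x %in% POLARITY_HYDROPHOBIC) "hydrophobic"
  else if (x %in% POLARITY_OTHER) "other"
  else stop(sprintf("not a residue: '%s'", x), call. = FALSE)
}

#' Physicochemical report for a sequence set
#'
#' @param seqs record data.frame (`id`, `desc`, `seq`).
#' @param pka pKa table.
#' @param pH pH for the reported net charge (default 7).
#' @return data.frame `sequence_id`, `mw_da`, `pi`, `charge_ph7`,
#'   `cxc_x`, `cxc_polarity` (CXC fields from the first motif candidate,
#'   `"."` when no motif).
#' @export
physchem_report <- function(seqs, pka = default_pka(), pH = 7) {
  do.call(rbind, lapply(seq_len(nrow(seqs)), function(i) {
    s <- seqs$seq[i]
    has_x <- grepl("X", s, fixed = TRUE)
    m <- find_cys_motifs(s)
    data.frame(
      sequence_id = seqs$id[i],
      mw_da = if (has_x) NA_real_ else molecular_weight(s),
      pi = as.numeric(isoelectric_point(s, pka)),
      charge_ph7 = net_charge(s, pH, pka),
      cxc_x = if (nrow(m)) m$cxc_x[1] else ".",
      cxc_polarity = if (nrow(m)) cxc_polarity(m$cxc_x[1]) else ".",
      stringsAsFactors = FALSE)
  }))
}
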