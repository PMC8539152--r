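## Synthetic designs and fixture molecules: everything the test suite and
## the simulation studies need is generated in code, deterministically
## under a seed.

#' Specification for a synthetic group-count design
#'
#' Describes a sparse non-negative occurrence matrix over an artificial
#' group vocabulary with known ("planted") contributions: group popularity
#' follows a Zipf profile, per-cell counts are Poisson, responses are
#' counts times truth plus Gaussian noise, and a fraction of records can
#' be turned into gross outliers.
#'
#' @param n_molecules number of records (rows).
#' @param n_groups vocabulary size (columns).
#' @param count_lambda mean Poisson count for the most popular group.
#' @param zipf_s Zipf exponent for the popularity profile (0 = uniform).
#' @param contribution_range range (kJ/mol) the planted contributions are
#'   drawn from uniformly.
#' @param noise_sd Gaussian noise standard deviation, kJ/mol.
#' @param outlier_fraction fraction of records perturbed into outliers.
#' @param outlier_magnitude outlier shift in units of \code{noise_sd}.
#' @param seed integer seed; the same spec always generates the same data.
#' @return a list of class \code{"SyntheticDesignSpec"}.
#' @export
syntheticDesignSpec <- function(n_molecules = 60L, n_groups = 8L,
                                count_lambda = 1.5, zipf_s = 0.8,
                                contribution_range = c(-2000, -100),
                                noise_sd = 5, outlier_fraction = 0,
                                outlier_magnitude = 10, seed = 1L) {
  if (n_groups < 1) stop("degenerate spec: empty vocabulary")
  if (n_molecules < 1) stop("degenerate spec: no molecules")
  structure(list(n_molecules = as.integer(n_molecules),
                 n_groups = as.integer(n_groups),
                 count_lambda = count_lambda, zipf_s = zipf_s,
                 contribution_range = contribution_range,
                 noise_sd = noise_sd,
                 outlier_fraction = outlier_fraction,
                 outlier_magnitude = outlier_magnitude,
                 seed = as.integer(seed)),
            class = "SyntheticDesignSpec")
}

#' Generate a synthetic design system with planted truth
#'
#' @param spec a \code{\link{syntheticDesignSpec}}.
#' @return list: \code{X} (occurrence matrix, every column has at least
#'   one non-zero and no row is all-zero), \code{y} (responses),
#'   \code{truth} (planted contributions), \code{outliers} (indices of
#'   perturbed records), \code{records} (the same data shaped for
#'   \code{\link{buildDesignSystem}}), \code{spec}.
#' @export
genDesign <- function(spec) {
  stopifnot(inherits(spec, "SyntheticDesignSpec"))
  withLocalSeed(spec$seed, {
    M <- spec$n_molecules; N <- spec$n_groups
    lam <- spec$count_lambda / (seq_len(N)^spec$zipf_s)
    X <- matrix(stats::rpois(M * N, rep(lam, each = M)), nrow = M)
    colnames(X) <- paste0("G", seq_len(N), "|syn")
    ## no empty row, no empty column
    for (i in which(rowSums(X) == 0))
      X[i, sample.int(N, 1)] <- 1
    for (j in which(colSums(X) == 0))
      X[sample.int(M, 1), j] <- 1
    truth <- stats::runif(N, min(spec$contribution_range),
                          max(spec$contribution_range))
    names(truth) <- colnames(X)
    y <- drop(X %*% truth) + stats::rnorm(M, 0, spec$noise_sd)
    n_out <- round(spec$outlier_fraction * M)
    outliers <- integer()
    if (n_out > 0) {
      outliers <- sort(sample.int(M, n_out))
      shift <- spec$outlier_magnitude * max(spec$noise_sd, 1) *
        sample(c(-1, 1), n_out, replace = TRUE)
      y[outliers] <- y[outliers] + shift
    }
    records <- lapply(seq_len(M), function(i) {
      cnt <- X[i, ]
      list(counts = cnt[cnt > 0], hc = y[i], name = paste0("syn", i))
    })
    list(X = X, y = y, truth = truth, outliers = outliers,
         records = records, spec = spec)
  })
}

diketene3dMolBlock <- function() {
  ## idealized planar four-ring (90 degree internal angles), bond length
  ## 1.5 A, with the exocyclic =CH2 and =O on the ring diagonal; a
  ## synthetic geometry, adequate for angle binning and contact checks
  atoms <- list(
    c(0, 0, "C"),          # C1: =CH2 carbon of the ring
    c(1.5, 0, "O"),        # ring O
    c(1.5, 1.5, "C"),      # carbonyl C
    c(0, 1.5, "C"),        # ring CH2
    c(-0.93, -0.93, "C"),  # exocyclic =CH2
    c(2.35, 2.35, "O"))    # carbonyl =O
  lines <- c("diketene", "  hcgroups", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 10, 10))
  coord <- function(x, y, z, el)
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            x, y, z, el)
  for (a in atoms) lines <- c(lines, coord(as.numeric(a[1]), as.numeric(a[2]), 0, a[3]))
  ## ring CH2 hydrogens out of plane, =CH2 hydrogens in plane
  lines <- c(lines,
             coord(-2.0, -0.93, 0, "H"), coord(-0.93, -2.0, 0, "H"),
             coord(-0.55, 2.05, 0.85, "H"), coord(-0.55, 2.05, -0.85, "H"))
  bonds <- rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 1, 1),
                 c(1, 5, 2), c(3, 6, 2),
                 c(5, 7, 1), c(5, 8, 1), c(4, 9, 1), c(4, 10, 1))
  for (k in seq_len(nrow(bonds)))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              bonds[k, 1], bonds[k, 2], bonds[k, 3]))
  c(lines, "M  END")
}

## a constructed two-alcohol fragment whose O-H points at the second
## oxygen from a tunable distance; used to exercise the H-bridge threshold
hbondPairMolecule <- function(d = 1.6) {
  atoms <- data.frame(
    element = c("O", "H", "O", "C", "C", "H"),
    charge = 0L,
    x = c(0, 0.96, 0.96 + d, -0.70, 0.96 + d + 0.70, 0.96 + d + 1.34),
    y = c(0, 0, 0, 1.20, 1.20, -0.70),
    z = 0,
    stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = c(1, 1, 3, 4, 3),
                      a2 = c(2, 4, 5, 5, 6),
                      order = "single", stringsAsFactors = FALSE)
  res <- addImplicitHydrogens(atoms, bonds)
  ## place the methylene hydrogens well apart so only the O-H...O pair
  ## can trigger special groups
  a <- res$atoms
  extra <- which(is.na(a$x))
  off <- cbind(c(-0.6, -0.6, 0.6, 0.6), c(0.7, 0.7, 0.7, 0.7),
               c(3, -3, 3, -3))
  for (k in seq_along(extra)) {
    parent <- res$bonds$a1[res$bonds$a2 == extra[k]]
    a$x[extra[k]] <- a$x[parent] + off[k, 1]
    a$y[extra[k]] <- a$y[parent] + off[k, 2]
    a$z[extra[k]] <- off[k, 3]
  }
  res$atoms <- a
  newMolecularGraph(res$atoms, res$bonds,
                    name = sprintf("hbond_pair_d%.2f", d), has3d = TRUE)
}

#' Named fixture molecules used throughout the tests and examples
#'
#' Small molecules with known decompositions and reference enthalpies:
#' the four-ring lactone worked example (diketene, also available as a
#' 3D MOL block with idealized square-ring geometry), hydrogen peroxide,
#' the keto/enol pairs (acetone, cyclohexanone, phenol), amino acids in
#' both prototropic forms (glycine, alanine, sarcosine), cyclopropane and
#' cyclohexanone for ring-strain behaviour, tetramethylammonium nitrate,
#' and a constructed 3D pair that switches an intramolecular H bridge on
#' and off across the 1.75 A threshold.
#'
#' @return named list of \linkS4class{MolecularGraph}.
#' @export
fixtureMolecules <- function() {
  smi <- c(
    diketene             = "C1(=C)OC(=O)C1",
    hydrogen_peroxide    = "OO",
    acetone              = "CC(=O)C",
    acetone_enol         = "CC(O)=C",
    cyclohexanone        = "O=C1CCCCC1",
    cyclohexanone_enol   = "OC1=CCCCC1",
    phenol               = "Oc1ccccc1",
    glycine_neutral      = "NCC(O)=O",
    glycine_zwitterion   = "[NH3+]CC([O-])=O",
    alanine_neutral      = "NC(C)C(O)=O",
    alanine_zwitterion   = "[NH3+]C(C)C([O-])=O",
    sarcosine_neutral    = "CNCC(O)=O",
    sarcosine_zwitterion = "C[NH2+]CC([O-])=O",
    n_phenylglycine      = "OC(=O)CNc1ccccc1",
    cyclopropane         = "C1CC1",
    cyclopentanone       = "O=C1CCCC1",
    tetramethylammonium_nitrate = "C[N+](C)(C)C.[O-][N+]([O-])=O")
  out <- lapply(names(smi), function(nm) parseSmiles(smi[[nm]], name = nm))
  names(out) <- names(smi)
  out$diketene_3d <- parseMolfile(diketene3dMolBlock())
  out$hbond_pair_on <- hbondPairMolecule(1.6)
  out$hbond_pair_off <- hbondPairMolecule(1.9)
  out
}

#' The packaged ionic-liquid reference suite
#'
#' 28 ionic liquids (imidazolium, ammonium, pyrrolidinium, guanidinium and
#' glycinium cations with nitrate, dicyanamide, halide, sulfate and
#' dithiocarbamate anions) with their experimental heats of combustion and
#' the reference calculated values and percentage deviations of the
#' published comparison, as packaged plain-text data.
#'
#' @return data.frame with columns \code{name}, \code{smiles},
#'   \code{hc_exp}, \code{hc_calc_ref}, \code{dev_pct_ref}.
#' @export
ionicLiquidSuite <- function() {
  path <- system.file("extdata", "ionic_liquids_reference.tsv",
                      package = "hcgroups", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}

#' Write a synthetic training table in the CSV schema the trainer reads
#'
#' @param spec a \code{\link{syntheticDesignSpec}}.
#' @param file output CSV path.
#' @return invisibly, the data.frame written (record name, group counts as
#'   a packed string, response).
#' @export
writeSyntheticTrainingCsv <- function(spec, file) {
  g <- genDesign(spec)
  packed <- apply(g$X, 1, function(r) {
    nz <- which(r > 0)
    paste(sprintf("%s:%d", colnames(g$X)[nz], r[nz]), collapse = ";")
  })
  d <- data.frame(name = vapply(g$records, `[[`, character(1), "name"),
                  groups = packed, hc_exp = g$y,
                  stringsAsFactors = FALSE)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(d)
}

#' Read a training CSV written by \code{\link{writeSyntheticTrainingCsv}}
#' @param file CSV path.
#' @return records list for \code{\link{buildDesignSystem}}.
#' @export
readTrainingCsv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    parts <- strsplit(d$groups[i], ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    cnt <- vapply(kv, function(p) as.integer(p[length(p)]), integer(1))
    names(cnt) <- vapply(kv, function(p)
      paste(p[-length(p)], collapse = ":"), character(1))
    list(counts = cnt, hc = d$hc_exp[i], name = d$name[i])
  })
}
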