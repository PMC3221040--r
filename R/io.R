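# NIfTI input, result tables and analysis configuration.

#' Read a 3D statistical map from NIfTI
#'
#' Reads a NIfTI-1/2 volume, returning the statistic lattice, the voxel
#' size and the affine. Non-finite voxels (NaN) are treated as out of
#' mask and returned as \code{NA}.
#'
#' @param path path to a NIfTI file.
#' @param volume for 4D files, which volume to extract; an error is
#'   raised if the file is 4D and \code{volume} is missing.
#' @return list with \code{map} (numeric array with \code{NA} out of
#'   mask), \code{voxelSize} (mm per axis) and \code{affine} (4x4
#'   voxel-to-mm matrix).
#' @export
readStatisticMap <- function(path, volume = NULL) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 4L) {
        if (is.null(volume))
            stop("4D input: supply `volume` to select one 3D map")
        img <- img[, , , volume]
        d <- dim(img)
    }
    if (length(d) != 3L) stop("expected a 3D statistical map")
    affine <- structure(RNifti::xform(img), class = NULL)
    if (any(!is.finite(affine))) stop("non-finite affine in NIfTI header")
    voxelSize <- RNifti::pixdim(img)[seq_len(3L)]
    map <- array(as.numeric(img), d)
    map[!is.finite(map)] <- NA_real_
    list(map = map, voxelSize = voxelSize, affine = affine)
}

#' Write a 3D array as NIfTI
#'
#' @param map numeric array (3D).
#' @param path output file path.
#' @param voxelSize mm per voxel, per axis.
#' @return the path, invisibly.
#' @export
writeStatisticMap <- function(map, path, voxelSize = 1) {
    voxelSize <- rep_len(voxelSize, 3L)
    img <- RNifti::asNifti(map)
    RNifti::pixdim(img) <- voxelSize
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Write a peak table as TSV
#'
#' Serialises the discovered peaks of a \code{\link{ProcedureResult}} to
#' a tab-separated table with a commented metadata header recording the
#' procedure, level, feature threshold, smoothness and resel counts.
#' Columns: mm coordinates, lattice indices, height, uncorrected p, FWE
#' p, q, cluster id and cluster extent; rows sorted by decreasing height.
#' Probabilities are reported to 6 decimals, statistic values to 4.
#'
#' @param result a \code{\link{ProcedureResult}}.
#' @param path output file.
#' @param space the \code{\link{SearchSpace}} the analysis used.
#' @param affine optional 4x4 voxel-to-mm affine; defaults to scaling by
#'   the voxel size (0-based voxel convention).
#' @return the path, invisibly.
#' @export
writePeakTable <- function(result, path, space, affine = NULL) {
    stopifnot(is(result, "ProcedureResult"), is(space, "SearchSpace"))
    pk <- peaks(result)
    if (is.null(affine)) {
        vs <- rep_len(space@voxelSize, 3L)
        affine <- diag(c(vs, 1))
    }
    xyz <- if (nrow(pk)) {
        v <- cbind(pk$i - 1, pk$j - 1, pk$k - 1, 1) %*% t(affine)
        round(v[, 1:3, drop = FALSE], 4)
    } else matrix(numeric(), 0, 3)
    extent <- if (nrow(pk) && nrow(result@clusters))
        result@clusters$nVoxels[match(pk$cluster, result@clusters$cluster)]
    else rep(NA_integer_, nrow(pk))
    tab <- data.frame(x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
        i = pk$i, j = pk$j, k = pk$k, height = round(pk$height, 4),
        p_unc = round(pk$p_unc, 6), p_fwe = round(pk$p_fwe, 6),
        q = round(pk$q, 6), cluster_id = pk$cluster,
        cluster_extent_voxels = extent)
    tab <- tab[order(-tab$height), , drop = FALSE]
    hdr <- c(
        sprintf("# procedure: %s", result@procedure),
        sprintf("# alpha: %g", result@alpha),
        sprintf("# u: %s", if (is.na(result@u)) "none" else
            format(round(result@u, 4))),
        sprintf("# adaptive_threshold: %g", result@adaptiveThreshold),
        sprintf("# n_harvested: %d", result@nHarvested),
        sprintf("# fwhm_mm: %s", paste(signif(space@fwhm, 6),
            collapse = " ")),
        sprintf("# resels: %s", paste(signif(space@resels, 6),
            collapse = " ")))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
        row.names = FALSE))
    invisible(path)
}

#' Read an analysis configuration (YAML)
#'
#' Reads and validates the configuration driving a map analysis: input
#' path, field family and degrees of freedom, smoothness (FWHM in mm or
#' a residual-stack path), feature threshold, level, procedures and
#' output directory.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
readAnalysisConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    need <- c("input", "family", "alpha", "procedures")
    miss <- setdiff(need, names(cfg))
    if (length(miss))
        stop("config is missing fields: ", paste(miss, collapse = ", "))
    if (cfg$family == "t" && is.null(cfg$dof))
        stop("t maps require `dof` in the config")
    topo <- setdiff(cfg$procedures, "voxel_fdr")
    if (length(topo) && is.null(cfg$u))
        stop("procedures ", paste(topo, collapse = ", "),
             " require a feature threshold `u`")
    if (is.null(cfg$fwhm) && is.null(cfg$residuals))
        stop("supply either `fwhm` (mm) or `residuals` (NIfTI stack path)")
    cfg
}

#' Analyze a statistical map with the four procedures
#'
#' End-to-end analysis of a precomputed statistic map: reads the NIfTI
#' volume, builds the search space from supplied smoothness (or estimates
#' it from a residual stack), runs the requested procedures and writes
#' one peak table per procedure.
#'
#' @param config list as returned by \code{\link{readAnalysisConfig}}.
#' @param outDir output directory (created if needed).
#' @return named list of \code{\link{ProcedureResult}}s, invisibly;
#'   tables are written to \code{outDir}.
#' @export
analyzeStatisticMap <- function(config, outDir = ".") {
    mp <- readStatisticMap(config$input, volume = config$volume)
    field <- FieldSpec(config$family,
        dof = if (is.null(config$dof)) NA_real_ else config$dof,
        dim = 3L)
    fwhm <- if (!is.null(config$fwhm)) rep_len(config$fwhm, 3L) else {
        res4 <- RNifti::readNifti(config$residuals)
        estimateFwhm(array(as.numeric(res4), dim(res4)),
                     voxelSize = mp$voxelSize)
    }
    space <- SearchSpace(dim(mp$map), fwhm = fwhm,
                         voxelSize = mp$voxelSize)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    procs <- config$procedures
    if (identical(procs, "all"))
        procs <- c("peak_fwe", "peak_fdr", "cluster_fdr", "voxel_fdr")
    out <- lapply(procs, function(p) {
        r <- runProcedure(mp$map, p,
            alpha = config$alpha, u = config$u, space = space,
            field = field,
            connectivity = if (is.null(config$connectivity)) 18L
                           else config$connectivity)
        writePeakTable(r, file.path(outDir, paste0("peaks_", p, ".tsv")),
                       space, affine = mp$affine)
        message(sprintf("%s: %d discovered peak(s) (of %d harvested)",
                        p, nrow(peaks(r)), r@nHarvested))
        r
    })
    invisible(setNames(out, procs))
}
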