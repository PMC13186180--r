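#' Read an FSL-style gradient table
#'
#' Parses `bval`/`bvec` text files, classifies measurements with
#' b <= 50 s/mm^2 as b = 0, clusters the remaining b-values into shells
#' (tolerance 100 s/mm^2), normalizes directions and converts units to
#' ms/um^2 (1000 s/mm^2 = 1 ms/um^2).
#'
#' @param bval_path Path to the b-value file (one row of numbers, s/mm^2).
#' @param bvec_path Path to the b-vector file (3 rows or 3 columns).
#' @param b0_thresh b = 0 classification threshold in s/mm^2 (default 50).
#' @param shell_tol Shell clustering tolerance in s/mm^2 (default 100).
#' @return An [acquisition_scheme()] with attributes `b0_cols` and
#'   `shell_cols` recording the original column indices.
#' @export
read_gradient_table <- function(bval_path, bvec_path, b0_thresh = 50,
                                shell_tol = 100) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- unname(as.matrix(utils::read.table(bvec_path)))
  # FSL convention is 3 rows x N columns; prefer it when both fit
  if (nrow(bv) == 3 && ncol(bv) == length(bvals)) bv <- t(bv)
  if (ncol(bv) != 3) stop("bvec file must have 3 rows or 3 columns")
  if (nrow(bv) != length(bvals))
    stop("bval and bvec files disagree on the number of measurements: ",
         length(bvals), " vs ", nrow(bv))
  b0 <- bvals <= b0_thresh
  dw <- which(!b0)
  if (any(sqrt(rowSums(bv[dw, , drop = FALSE]^2)) < 1e-6))
    stop("zero-norm gradient direction with b > ", b0_thresh)
  # cluster diffusion-weighted b-values into shells
  ub <- sort(unique(bvals[dw]))
  centers <- c(); assign_c <- numeric(0)
  for (b in ub) {
    if (length(centers) == 0 || b - centers[length(centers)] > shell_tol)
      centers <- c(centers, b)
  }
  shell_of <- vapply(bvals[dw], function(b)
    which.min(abs(centers - b)), integer(1))
  dirs <- unname(normalize_rows(bv[dw, , drop = FALSE]))
  shell_cols <- lapply(seq_along(centers), function(k) dw[shell_of == k])
  shell_bvals <- vapply(seq_along(centers), function(k)
    mean(bvals[shell_cols[[k]]]), numeric(1))
  scheme <- acquisition_scheme(
    shell_bvals / 1000,
    lapply(seq_along(centers), function(k)
      dirs[shell_of == k, , drop = FALSE]),
    n_b0 = sum(b0))
  attr(scheme, "b0_cols") <- which(b0)
  attr(scheme, "shell_cols") <- shell_cols
  scheme
}

#' Write an FSL-style gradient table
#'
#' Inverse of [read_gradient_table()] for round-tripping synthetic designs:
#' b = 0 columns first, then the shells in order.
#'
#' @param scheme An [acquisition_scheme()].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  bvals <- c(rep(0, scheme$n_b0),
             unlist(lapply(scheme$shells, function(sh)
               rep(sh$b * 1000, nrow(sh$dirs)))))
  dirs <- rbind(matrix(0, scheme$n_b0, 3),
                do.call(rbind, lapply(scheme$shells, `[[`, "dirs")))
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bval_path)
  utils::write.table(t(dirs), bvec_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(bval_path, bvec_path))
}

#' Read a 4D diffusion volume into per-voxel signal samples
#'
#' Loads a NIfTI volume, normalizes each masked voxel by its mean b = 0
#' signal and groups the diffusion-weighted measurements into the scheme's
#' shells. Voxels with nonpositive mean b = 0 are excluded with a warning.
#'
#' @param dwi_path Path to the 4D NIfTI volume.
#' @param scheme Scheme from [read_gradient_table()] (needs its column
#'   attributes).
#' @param mask_path Optional path to a 3D mask volume (nonzero = included).
#' @return A list with `signals` (list of `signal_sample`), `voxels`
#'   (matrix of array indices), `dim` and the image header (for writing
#'   results back).
#' @export
read_dwi <- function(dwi_path, scheme, mask_path = NULL) {
  img <- RNifti::readNifti(dwi_path)
  d <- dim(img)
  if (length(d) != 4) stop("expected a 4D diffusion volume")
  b0_cols <- attr(scheme, "b0_cols")
  shell_cols <- attr(scheme, "shell_cols")
  if (is.null(b0_cols) || is.null(shell_cols))
    stop("scheme lacks gradient-table column attributes; ",
         "use read_gradient_table()")
  n_meas <- length(b0_cols) + sum(lengths(shell_cols))
  if (d[4] != n_meas)
    stop("4th dimension (", d[4], ") does not match the gradient table (",
         n_meas, ")")
  mask <- if (is.null(mask_path)) array(TRUE, d[1:3])
    else array(as.vector(RNifti::readNifti(mask_path)) != 0, d[1:3])
  vox <- which(mask, arr.ind = TRUE)
  mat <- matrix(img, prod(d[1:3]), d[4])
  lin <- (vox[, 3] - 1) * d[1] * d[2] + (vox[, 2] - 1) * d[1] + vox[, 1]
  b0_mean <- rowMeans(mat[lin, b0_cols, drop = FALSE])
  ok <- b0_mean > 0
  if (any(!ok))
    warning(sum(!ok), " voxel(s) with nonpositive mean b = 0 excluded")
  vox <- vox[ok, , drop = FALSE]; lin <- lin[ok]; b0_mean <- b0_mean[ok]
  signals <- lapply(seq_along(lin), function(i) {
    structure(list(s = lapply(shell_cols, function(cols)
      mat[lin[i], cols] / b0_mean[i])), class = "signal_sample")
  })
  list(signals = signals, voxels = vox, dim = d[1:3], header = img,
       b0 = mat[lin, b0_cols, drop = FALSE] / b0_mean)
}

#' Voxel-grid inference driver
#'
#' Reads a 4D diffusion volume with its gradient table and mask, estimates
#' the noise variance from the b = 0 images, runs the per-voxel sequential
#' inference, and writes parameter and uncertainty maps (fiber count,
#' per-fiber posterior-mean kernel parameters, detection rate and angular
#' dispersion) plus the estimated ODF field as a symmetric
#' spherical-harmonic coefficient volume (degree 20, 231 coefficients,
#' zero-padded beyond the model's band limit).
#'
#' @param dwi_path,bval_path,bvec_path,mask_path Input files.
#' @param inverter,mdn_models Trained models.
#' @param out_dir Output directory (created).
#' @param Q,B,alpha,seed Inference settings (desk-scale defaults).
#' @return Invisibly, the output directory.
#' @export
infer_volume <- function(dwi_path, bval_path, bvec_path, mask_path = NULL,
                         inverter, mdn_models, out_dir,
                         Q = 1000, B = 100, alpha = 0.05, seed = 1L) {
  scheme <- read_gradient_table(bval_path, bvec_path)
  dwi <- read_dwi(dwi_path, scheme, mask_path)
  sigma_e2 <- estimate_sigma_e(dwi$b0)
  nvox <- length(dwi$signals)
  d3 <- dwi$dim
  nmap <- array(0, d3)
  pm_maps <- array(NA_real_, c(d3, 3, 5))
  dr_map <- ad_map <- array(NA_real_, c(d3, 3))
  K20 <- sh_basis(20)$K
  sh_map <- array(0, c(d3, K20))
  ops <- inverter_ops(inverter)
  ops_out <- mesh_sh_operators(ops$mesh, ops$basis_out)
  idx20 <- which(sh_basis(20)$l %in% unique(ops$basis_out$l) &
                   abs(sh_basis(20)$m) <= sh_basis(20)$l)
  # map model coefficients into the degree-20 system by matching (l, m)
  key20 <- paste(sh_basis(20)$l, sh_basis(20)$m)
  key_out <- paste(ops$basis_out$l, ops$basis_out$m)
  pos <- match(key_out, key20)
  for (i in seq_len(nvox)) {
    v <- dwi$voxels[i, ]
    res <- run_inference(dwi$signals[[i]], scheme, inverter, mdn_models,
                         sigma_e2, Q = Q, B = B, alpha = alpha,
                         seed = seed + i)
    nmap[v[1], v[2], v[3]] <- res$n
    co <- ops_out$analysis %*% res$odf$g
    sh_map[v[1], v[2], v[3], pos] <- co
    if (res$n > 0) {
      for (fi in seq_len(res$n)) {
        pm_maps[v[1], v[2], v[3], fi, ] <- res$pm[[fi]]
        dr_map[v[1], v[2], v[3], fi] <- res$dr[fi]
        ad_map[v[1], v[2], v[3], fi] <- res$ad[fi]
      }
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tmpl <- RNifti::readNifti(dwi_path)
  wr <- function(arr, name) {
    RNifti::writeNifti(RNifti::asNifti(arr, reference = tmpl),
                       file.path(out_dir, name))
  }
  wr(nmap, "nfibers.nii.gz")
  par_names <- c("Da", "De_par", "De_perp", "z1", "z2")
  for (p in seq_along(par_names))
    wr(pm_maps[, , , , p], paste0("pm_", par_names[p], ".nii.gz"))
  wr(dr_map, "dr.nii.gz")
  wr(ad_map, "ad.nii.gz")
  wr(sh_map, "odf_sh.nii.gz")
  jsonlite::write_json(
    list(sigma_e2 = sigma_e2, Q = Q, B = B, alpha = alpha, seed = seed,
         n_voxels = nvox),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
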