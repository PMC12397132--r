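# shared fixtures, built in code at test time

default_sched <- make_default_schedule()
default_inp <- default_input_function()

# minimal hand-built phantom_spec for targeted synthesis tests
tiny_phantom <- function(labels, label_table, voxel_size = c(4, 4, 8)) {
  structure(list(labels = labels, label_table = label_table,
                 voxel_size = voxel_size),
            class = "phantom_spec")
}

liver_params <- kinetic_params(0.10, 0.34, 0.04, 0.33)

# a small 4D dynamic image whose voxels follow given frame curves
dyn_from_curves <- function(curves, grid = c(4, 4, 1),
                            schedule = default_sched) {
  nvox <- prod(grid)
  stopifnot(nrow(curves) == nvox)
  dynamic_image(array(as.vector(curves), c(grid, schedule$n_frames)),
                schedule)
}

# frame-averaged model TAC for a parameter vector
model_tac <- function(K1, k2, k3, vb, inp = default_inp,
                      schedule = default_sched) {
  tg <- seq(0, schedule_end_s(schedule)) / 60
  curve <- tcm2_tissue_concentration(kinetic_params(K1, k2, k3, vb), inp, tg)
  frame_average(tg, curve, schedule)
}
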