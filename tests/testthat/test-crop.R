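test_that("plane projections match the brute-force per-pixel maximum", {
  vol <- random_volume(c(5, 6, 7), seed = 11)
  cor_mip <- plane_mip(vol, "coronal")
  sag_mip <- plane_mip(vol, "sagittal")
  v <- vol$voxels
  for (i in 1:5) for (k in 1:7) {
    expect_identical(cor_mip[i, k], max(v[i, , k]))
  }
  for (j in 1:6) for (k in 1:7) {
    expect_identical(sag_mip[j, k], max(v[, j, k]))
  }

  const <- image_volume(array(4.2, c(3, 3, 3)))
  expect_true(all(plane_mip(const, "coronal") == 4.2))

  hot <- array(0, c(6, 7, 8)); hot[3, 5, 6] <- 9
  hv <- image_volume(hot)
  hm <- plane_mip(hv, "coronal")
  expect_equal(sum(hm != 0), 1L)
  expect_equal(hm[3, 6], 9)
})

test_that("XML and JSON box files parse, round-trip and validate", {
  xml <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<annotation>",
    " <size><width>128</width><height>128</height></size>",
    " <object><name>coronal</name>",
    "  <bndbox><xmin>10</xmin><ymin>30</ymin><xmax>20</xmax><ymax>90</ymax></bndbox>",
    " </object>",
    "</annotation>"), xml)
  boxes <- load_boxes_2d(xml)
  expect_length(boxes, 1L)
  b <- boxes[[1]]
  expect_equal(unclass(b)[c("plane", "u_min", "u_max", "v_min", "v_max")],
               list(plane = "coronal", u_min = 10L, u_max = 20L,
                    v_min = 30L, v_max = 90L))

  js <- withr::local_tempfile(fileext = ".json")
  orig <- list(bbox_2d("coronal", 10, 20, 30, 90, 128, 128),
               bbox_2d("sagittal", 5, 100, 0, 64, 128, 128))
  write_boxes_2d(orig, js)
  back <- load_boxes_2d(js)
  expect_equal(back, orig)

  expect_error(bbox_2d("coronal", 10, 200, 30, 90, 128, 128), "outside")
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<annotation><size><width>64</width><height>64</height></size>",
               "<object><name>coronal</name>",
               "<bndbox><xmin>1</xmin><ymin>2</ymin><xmax>99</xmax><ymax>9</ymax></bndbox>",
               "</object></annotation>"), bad)
  expect_error(load_boxes_2d(bad), "outside")
})

test_that("landmark heuristic keys on the shoulder row and head column", {
  img <- synthetic_bone_mip(128, 128, col_span = c(51, 70),
                            shoulder_row = 80)
  prop <- propose_boxes_heuristic(img, img, margin = 4)
  b <- prop$coronal
  # vertical extent starts at the shoulder bar (rows 80..82, 1-based)
  expect_lte(abs(b$v_min - 81), 2)
  expect_equal(b$v_max, 120)             # topmost bone row (128 - 8)
  # horizontal extent contains the constructed head column [50, 70)
  expect_lte(b$u_min, 50)
  expect_gte(b$u_max, 70)
  expect_lte(50 - b$u_min, 4 + 1)        # and not much more than the margin

  expect_error(propose_boxes_heuristic(matrix(0, 8, 8), matrix(0, 8, 8)),
               "no bone")
})

test_that("2D boxes combine into the expected 3D box", {
  cor_box <- bbox_2d("coronal", 10, 90, 5, 100, 128, 128)
  sag_box <- bbox_2d("sagittal", 20, 80, 8, 95, 128, 128)
  b3 <- combine_boxes_3d(cor_box, sag_box, c(128, 128, 128))
  expect_equal(unclass(b3)[c("x_min", "x_max", "y_min", "y_max",
                             "z_min", "z_max")],
               list(x_min = 10L, x_max = 90L, y_min = 20L, y_max = 80L,
                    z_min = 5L, z_max = 100L))

  # identical v-extents reproduce that extent; full planes give full volume
  sag2 <- bbox_2d("sagittal", 20, 80, 5, 100, 128, 128)
  b32 <- combine_boxes_3d(cor_box, sag2, c(128, 128, 128))
  expect_equal(c(b32$z_min, b32$z_max), c(5L, 100L))
  full_c <- bbox_2d("coronal", 0, 64, 0, 32, 64, 32)
  full_s <- bbox_2d("sagittal", 0, 64, 0, 32, 64, 32)
  bf <- combine_boxes_3d(full_c, full_s, c(64, 64, 32))
  expect_equal(c(bf$x_max, bf$y_max, bf$z_max), c(64L, 64L, 32L))

  inter <- combine_boxes_3d(cor_box, sag_box, c(128, 128, 128),
                            z_rule = "intersection")
  expect_equal(c(inter$z_min, inter$z_max), c(8L, 95L))

  expect_error(combine_boxes_3d(sag_box, sag_box, c(128, 128, 128)),
               "coronal")
})

test_that("cropping equals index slicing and shifts the origin", {
  vol <- random_volume(c(12, 10, 14), seed = 7, spacing = c(1, 2, 3))
  full <- crop_volume(vol, bbox_3d(0, 12, 0, 10, 0, 14))
  expect_identical(full$voxels, vol$voxels)

  unit <- crop_volume(vol, bbox_3d(3, 4, 5, 6, 7, 8))
  expect_equal(dim(unit$voxels), c(1L, 1L, 1L))
  expect_identical(unit$voxels[1, 1, 1], vol$voxels[4, 6, 8])

  set.seed(21)
  for (i in 1:5) {
    lo <- c(sample(0:5, 1), sample(0:4, 1), sample(0:6, 1))
    hi <- lo + c(sample(1:6, 1), sample(1:5, 1), sample(1:7, 1))
    box <- bbox_3d(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3])
    cr <- crop_volume(vol, box)
    expect_identical(cr$voxels,
                     vol$voxels[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                                (lo[3] + 1):hi[3], drop = FALSE])
    expect_equal(cr$origin, vol$origin + lo * vol$spacing)
    # every cropped voxel sits at the predicted offset in the source
    expect_identical(cr$voxels[1, 1, 1],
                     vol$voxels[lo[1] + 1, lo[2] + 1, lo[3] + 1])
  }
  expect_error(crop_volume(vol, bbox_3d(20, 25, 0, 5, 0, 5)), "empty")
})

test_that("boxes map between registered grids through physical space", {
  ct <- image_volume(array(0, c(64, 64, 64)), spacing = c(1, 1, 1))
  pet <- image_volume(array(0, c(32, 32, 32)), spacing = c(2, 2, 2))
  box <- bbox_3d(10, 30, 12, 40, 8, 48)
  mapped <- map_box_grid(box, ct, pet)
  # a 1 mm-grid index maps to roughly half its value on the 2 mm grid
  expect_lte(abs(mapped$x_min - 5), 1)
  expect_lte(abs(mapped$x_max - 15), 1)
  expect_lte(abs(mapped$z_max - 24), 1)
})
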