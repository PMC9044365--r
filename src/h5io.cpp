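// Minimal HDF5 bindings for the fastMRI volume dialect: dataset "kspace"
// stored as complex64 (compound {r, i} of float32) with file layout
// (slices, coils, rows, columns), optional dataset "reconstruction_rss"
// stored as float32 (slices, rows, columns), and scalar string attributes on
// the root group.  On the R side k-space arrays use dim c(rows, columns,
// coils, slices); the transposition between the two layouts happens here.
#include <Rcpp.h>
#include <hdf5.h>
#include <string>
#include <vector>

static hid_t complex64_type() {
  hid_t t = H5Tcreate(H5T_COMPOUND, 2 * sizeof(float));
  H5Tinsert(t, "r", 0, H5T_NATIVE_FLOAT);
  H5Tinsert(t, "i", sizeof(float), H5T_NATIVE_FLOAT);
  return t;
}

static void quiet_errors() { H5Eset_auto2(H5E_DEFAULT, NULL, NULL); }

// [[Rcpp::export(name = ".h5_write_volume")]]
void h5_write_volume(std::string path, Rcpp::ComplexVector kspace,
                     Rcpp::IntegerVector kdim, Rcpp::NumericVector rss,
                     Rcpp::IntegerVector rdim, Rcpp::CharacterVector attrs) {
  quiet_errors();
  hid_t file = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  if (file < 0) Rcpp::stop("cannot create HDF5 file '%s'", path);
  const hsize_t R = kdim[0], W = kdim[1], C = kdim[2], S = kdim[3];

  {  // kspace: file layout (S, C, R, W), complex64
    hsize_t dims[4] = {S, C, R, W};
    hid_t space = H5Screate_simple(4, dims, NULL);
    hid_t ctype = complex64_type();
    hid_t dset = H5Dcreate2(file, "kspace", ctype, space, H5P_DEFAULT,
                            H5P_DEFAULT, H5P_DEFAULT);
    std::vector<float> buf(2 * S * C * R * W);
    for (hsize_t s = 0; s < S; s++)
      for (hsize_t c = 0; c < C; c++)
        for (hsize_t r = 0; r < R; r++)
          for (hsize_t w = 0; w < W; w++) {
            const Rcomplex z = kspace[r + R * (w + W * (c + C * s))];
            const size_t o = 2 * (((s * C + c) * R + r) * W + w);
            buf[o] = (float)z.r;
            buf[o + 1] = (float)z.i;
          }
    H5Dwrite(dset, ctype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data());
    H5Dclose(dset); H5Tclose(ctype); H5Sclose(space);
  }

  if (rss.size() > 0) {  // reconstruction_rss: (S, R, W), float32
    const hsize_t rR = rdim[0], rW = rdim[1], rS = rdim[2];
    hsize_t dims[3] = {rS, rR, rW};
    hid_t space = H5Screate_simple(3, dims, NULL);
    hid_t dset = H5Dcreate2(file, "reconstruction_rss", H5T_NATIVE_FLOAT,
                            space, H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    std::vector<float> buf(rS * rR * rW);
    for (hsize_t s = 0; s < rS; s++)
      for (hsize_t r = 0; r < rR; r++)
        for (hsize_t w = 0; w < rW; w++)
          buf[(s * rR + r) * rW + w] = (float)rss[r + rR * (w + rW * s)];
    H5Dwrite(dset, H5T_NATIVE_FLOAT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
             buf.data());
    H5Dclose(dset); H5Sclose(space);
  }

  Rcpp::CharacterVector nm = attrs.names();
  hid_t root = H5Gopen2(file, "/", H5P_DEFAULT);
  for (int i = 0; i < attrs.size(); i++) {
    std::string val = Rcpp::as<std::string>(attrs[i]);
    std::string key = Rcpp::as<std::string>(nm[i]);
    hid_t stype = H5Tcopy(H5T_C_S1);
    H5Tset_size(stype, H5T_VARIABLE);
    H5Tset_cset(stype, H5T_CSET_UTF8);
    hid_t space = H5Screate(H5S_SCALAR);
    hid_t attr = H5Acreate2(root, key.c_str(), stype, space, H5P_DEFAULT,
                            H5P_DEFAULT);
    const char* cval = val.c_str();
    H5Awrite(attr, stype, &cval);
    H5Aclose(attr); H5Sclose(space); H5Tclose(stype);
  }
  H5Gclose(root);
  H5Fclose(file);
}

// [[Rcpp::export(name = ".h5_read_volume")]]
Rcpp::List h5_read_volume(std::string path) {
  quiet_errors();
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) Rcpp::stop("cannot open HDF5 file '%s'", path);
  if (H5Lexists(file, "kspace", H5P_DEFAULT) <= 0) {
    H5Fclose(file);
    Rcpp::stop("file '%s' has no dataset 'kspace'; expected the fastMRI "
               "layout: complex dataset 'kspace' of shape "
               "(slices, coils, rows, columns)", path);
  }
  hid_t dset = H5Dopen2(file, "kspace", H5P_DEFAULT);
  hid_t space = H5Dget_space(dset);
  int nd = H5Sget_simple_extent_ndims(space);
  if (nd != 4) {
    H5Sclose(space); H5Dclose(dset); H5Fclose(file);
    Rcpp::stop("dataset 'kspace' has %d dimensions; expected 4 "
               "(slices, coils, rows, columns)", nd);
  }
  hsize_t dims[4];
  H5Sget_simple_extent_dims(space, dims, NULL);
  const hsize_t S = dims[0], C = dims[1], R = dims[2], W = dims[3];
  hid_t ctype = complex64_type();
  std::vector<float> buf(2 * S * C * R * W);
  if (H5Dread(dset, ctype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data()) < 0) {
    H5Tclose(ctype); H5Sclose(space); H5Dclose(dset); H5Fclose(file);
    Rcpp::stop("dataset 'kspace' could not be read as complex values");
  }
  H5Tclose(ctype); H5Sclose(space); H5Dclose(dset);
  Rcpp::ComplexVector ks(S * C * R * W);
  for (hsize_t s = 0; s < S; s++)
    for (hsize_t c = 0; c < C; c++)
      for (hsize_t r = 0; r < R; r++)
        for (hsize_t w = 0; w < W; w++) {
          const size_t o = 2 * (((s * C + c) * R + r) * W + w);
          Rcomplex z; z.r = buf[o]; z.i = buf[o + 1];
          ks[r + R * (w + W * (c + C * s))] = z;
        }
  ks.attr("dim") = Rcpp::IntegerVector::create(R, W, C, S);

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("kspace") = ks);

  if (H5Lexists(file, "reconstruction_rss", H5P_DEFAULT) > 0) {
    hid_t rd = H5Dopen2(file, "reconstruction_rss", H5P_DEFAULT);
    hid_t rs = H5Dget_space(rd);
    hsize_t rdims[3];
    if (H5Sget_simple_extent_ndims(rs) == 3) {
      H5Sget_simple_extent_dims(rs, rdims, NULL);
      const hsize_t rS = rdims[0], rR = rdims[1], rW = rdims[2];
      std::vector<float> rbuf(rS * rR * rW);
      H5Dread(rd, H5T_NATIVE_FLOAT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
              rbuf.data());
      Rcpp::NumericVector rss(rS * rR * rW);
      for (hsize_t s = 0; s < rS; s++)
        for (hsize_t r = 0; r < rR; r++)
          for (hsize_t w = 0; w < rW; w++)
            rss[r + rR * (w + rW * s)] = rbuf[(s * rR + r) * rW + w];
      rss.attr("dim") = Rcpp::IntegerVector::create(rR, rW, rS);
      out["rss"] = rss;
    }
    H5Sclose(rs); H5Dclose(rd);
  }

  // root-group scalar string attributes
  hid_t root = H5Gopen2(file, "/", H5P_DEFAULT);
  int num_attrs = H5Aget_num_attrs(root);
  if (num_attrs < 0) num_attrs = 0;
  std::vector<std::string> keys, vals;
  for (hsize_t i = 0; i < (hsize_t)num_attrs; i++) {
    hid_t attr = H5Aopen_by_idx(root, ".", H5_INDEX_NAME, H5_ITER_NATIVE, i,
                                H5P_DEFAULT, H5P_DEFAULT);
    char name[256];
    H5Aget_name(attr, sizeof(name), name);
    hid_t atype = H5Aget_type(attr);
    if (H5Tget_class(atype) == H5T_STRING) {
      hid_t mtype = H5Tget_native_type(atype, H5T_DIR_ASCEND);
      if (H5Tis_variable_str(atype)) {
        char* sval = NULL;
        if (H5Aread(attr, mtype, &sval) >= 0 && sval != NULL) {
          keys.push_back(name); vals.push_back(sval);
          free(sval);
        }
      } else {
        size_t sz = H5Tget_size(atype);
        std::vector<char> sval(sz + 1, 0);
        if (H5Aread(attr, mtype, sval.data()) >= 0) {
          keys.push_back(name); vals.push_back(sval.data());
        }
      }
      H5Tclose(mtype);
    }
    H5Tclose(atype); H5Aclose(attr);
  }
  H5Gclose(root);
  H5Fclose(file);

  Rcpp::CharacterVector av(vals.size());
  Rcpp::CharacterVector an(vals.size());
  for (size_t i = 0; i < vals.size(); i++) {
    av[i] = vals[i]; an[i] = keys[i];
  }
  av.names() = an;
  out["attrs"] = av;
  return out;
}
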