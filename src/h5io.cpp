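// Minimal HDF5 I/O over the libhdf5 C API: numeric arrays (double),
// variable-length UTF-8 strings, group listing, existence/delete, and
// gzip-compressed dataset creation (used for store repacking).
//
// Array dimension convention: R dims are reversed on disk so that the fastest
// varying R index is the fastest varying index in the file; round trips within
// the package are exact, and row-major readers (h5py) see the transposed view
// (same convention as the common R HDF5 bindings).
#include <Rcpp.h>
#include <hdf5.h>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

struct Hid {
  hid_t id;
  herr_t (*closer)(hid_t);
  Hid(hid_t i, herr_t (*c)(hid_t)) : id(i), closer(c) {}
  ~Hid() { if (id >= 0 && closer) closer(id); }
};

void silence_errors() { H5Eset_auto2(H5E_DEFAULT, NULL, NULL); }

hid_t open_or_create(const std::string &file) {
  silence_errors();
  hid_t fid = -1;
  FILE *fp = fopen(file.c_str(), "rb");
  if (fp) { fclose(fp); fid = H5Fopen(file.c_str(), H5F_ACC_RDWR, H5P_DEFAULT); }
  if (fid < 0) fid = H5Fcreate(file.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  if (fid < 0) stop("cannot open or create HDF5 file '%s'", file);
  return fid;
}

hid_t open_readonly(const std::string &file) {
  silence_errors();
  hid_t fid = H5Fopen(file.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (fid < 0) stop("cannot open HDF5 file '%s'", file);
  return fid;
}

// does every component of `path` exist?
bool path_exists(hid_t fid, const std::string &path) {
  if (path.empty() || path == "/") return true;
  std::string part;
  size_t start = (path[0] == '/') ? 1 : 0;
  for (size_t i = start; i <= path.size(); ++i) {
    if (i == path.size() || path[i] == '/') {
      if (!part.empty()) {
        if (H5Lexists(fid, part.c_str(), H5P_DEFAULT) <= 0) return false;
      }
      if (i < path.size()) part += '/';
    } else {
      part += path[i];
    }
  }
  return true;
}

void remove_if_exists(hid_t fid, const std::string &path) {
  if (path_exists(fid, path))
    H5Ldelete(fid, path.c_str(), H5P_DEFAULT);
}

} // namespace

// [[Rcpp::export(name = ".h5_write_num")]]
void h5_write_num(std::string file, std::string path, NumericVector values,
                  IntegerVector dims, int compress = 0) {
  Hid fid(open_or_create(file), H5Fclose);
  remove_if_exists(fid.id, path);

  int nd = dims.size();
  std::vector<hsize_t> hdims(nd);
  for (int i = 0; i < nd; ++i) hdims[i] = (hsize_t)dims[nd - 1 - i]; // reversed
  Hid space(H5Screate_simple(nd, hdims.data(), NULL), H5Sclose);
  if (space.id < 0) stop("bad dataspace for '%s'", path);

  Hid lcpl(H5Pcreate(H5P_LINK_CREATE), H5Pclose);
  H5Pset_create_intermediate_group(lcpl.id, 1);
  Hid dcpl(H5Pcreate(H5P_DATASET_CREATE), H5Pclose);
  if (compress > 0 && values.size() > 0) {
    H5Pset_chunk(dcpl.id, nd, hdims.data());
    H5Pset_deflate(dcpl.id, (unsigned)compress);
  }
  Hid dset(H5Dcreate2(fid.id, path.c_str(), H5T_IEEE_F64LE, space.id,
                      lcpl.id, dcpl.id, H5P_DEFAULT), H5Dclose);
  if (dset.id < 0) stop("cannot create dataset '%s'", path);
  if (values.size() > 0) {
    herr_t st = H5Dwrite(dset.id, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL,
                         H5P_DEFAULT, REAL(values));
    if (st < 0) stop("write failed for '%s'", path);
  }
}

// [[Rcpp::export(name = ".h5_read_num")]]
NumericVector h5_read_num(std::string file, std::string path) {
  Hid fid(open_readonly(file), H5Fclose);
  if (!path_exists(fid.id, path)) stop("no such dataset: '%s'", path);
  Hid dset(H5Dopen2(fid.id, path.c_str(), H5P_DEFAULT), H5Dclose);
  if (dset.id < 0) stop("cannot open dataset '%s'", path);
  Hid space(H5Dget_space(dset.id), H5Sclose);
  int nd = H5Sget_simple_extent_ndims(space.id);
  std::vector<hsize_t> hdims(nd > 0 ? nd : 1);
  H5Sget_simple_extent_dims(space.id, hdims.data(), NULL);
  R_xlen_t n = 1;
  for (int i = 0; i < nd; ++i) n *= (R_xlen_t)hdims[i];
  NumericVector out(n);
  if (n > 0) {
    herr_t st = H5Dread(dset.id, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL,
                        H5P_DEFAULT, REAL(out));
    if (st < 0) stop("read failed for '%s'", path);
  }
  if (nd > 1) {
    IntegerVector rdims(nd);
    for (int i = 0; i < nd; ++i) rdims[i] = (int)hdims[nd - 1 - i]; // un-reverse
    out.attr("dim") = rdims;
  }
  return out;
}

// [[Rcpp::export(name = ".h5_write_str")]]
void h5_write_str(std::string file, std::string path, CharacterVector values) {
  Hid fid(open_or_create(file), H5Fclose);
  remove_if_exists(fid.id, path);
  hsize_t n = (hsize_t)values.size();
  Hid space(H5Screate_simple(1, &n, NULL), H5Sclose);
  Hid stype(H5Tcopy(H5T_C_S1), H5Tclose);
  H5Tset_size(stype.id, H5T_VARIABLE);
  H5Tset_cset(stype.id, H5T_CSET_UTF8);
  Hid lcpl(H5Pcreate(H5P_LINK_CREATE), H5Pclose);
  H5Pset_create_intermediate_group(lcpl.id, 1);
  Hid dset(H5Dcreate2(fid.id, path.c_str(), stype.id, space.id,
                      lcpl.id, H5P_DEFAULT, H5P_DEFAULT), H5Dclose);
  if (dset.id < 0) stop("cannot create string dataset '%s'", path);
  std::vector<std::string> keep(values.size());
  std::vector<const char *> ptrs(values.size());
  for (R_xlen_t i = 0; i < values.size(); ++i) {
    keep[i] = as<std::string>(values[i]);
    ptrs[i] = keep[i].c_str();
  }
  if (n > 0) {
    herr_t st = H5Dwrite(dset.id, stype.id, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                         ptrs.data());
    if (st < 0) stop("string write failed for '%s'", path);
  }
}

// [[Rcpp::export(name = ".h5_read_str")]]
CharacterVector h5_read_str(std::string file, std::string path) {
  Hid fid(open_readonly(file), H5Fclose);
  if (!path_exists(fid.id, path)) stop("no such dataset: '%s'", path);
  Hid dset(H5Dopen2(fid.id, path.c_str(), H5P_DEFAULT), H5Dclose);
  Hid space(H5Dget_space(dset.id), H5Sclose);
  hsize_t n = 0;
  int nd = H5Sget_simple_extent_ndims(space.id);
  if (nd > 0) H5Sget_simple_extent_dims(space.id, &n, NULL);
  else n = 1;
  Hid stype(H5Tcopy(H5T_C_S1), H5Tclose);
  H5Tset_size(stype.id, H5T_VARIABLE);
  H5Tset_cset(stype.id, H5T_CSET_UTF8);
  std::vector<char *> buf(n, NULL);
  if (n > 0) {
    herr_t st = H5Dread(dset.id, stype.id, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                        buf.data());
    if (st < 0) stop("string read failed for '%s'", path);
  }
  CharacterVector out((R_xlen_t)n);
  for (hsize_t i = 0; i < n; ++i) out[i] = buf[i] ? std::string(buf[i]) : "";
  H5Dvlen_reclaim(stype.id, space.id, H5P_DEFAULT, buf.data());
  return out;
}

// [[Rcpp::export(name = ".h5_ls")]]
List h5_ls(std::string file, std::string path) {
  Hid fid(open_readonly(file), H5Fclose);
  if (!path_exists(fid.id, path)) stop("no such group: '%s'", path);
  Hid grp(H5Gopen2(fid.id, path.empty() ? "/" : path.c_str(), H5P_DEFAULT),
          H5Gclose);
  if (grp.id < 0) stop("cannot open group '%s'", path);
  H5G_info_t info;
  H5Gget_info(grp.id, &info);
  CharacterVector names((R_xlen_t)info.nlinks);
  LogicalVector isgrp((R_xlen_t)info.nlinks);
  for (hsize_t i = 0; i < info.nlinks; ++i) {
    ssize_t len = H5Lget_name_by_idx(grp.id, ".", H5_INDEX_NAME, H5_ITER_INC,
                                     i, NULL, 0, H5P_DEFAULT);
    std::vector<char> nm(len + 1);
    H5Lget_name_by_idx(grp.id, ".", H5_INDEX_NAME, H5_ITER_INC, i, nm.data(),
                       len + 1, H5P_DEFAULT);
    names[(R_xlen_t)i] = std::string(nm.data());
    H5O_info_t oinfo;
#if H5_VERSION_GE(1, 12, 0)
    H5Oget_info_by_idx3(grp.id, ".", H5_INDEX_NAME, H5_ITER_INC, i, &oinfo,
                        H5O_INFO_BASIC, H5P_DEFAULT);
#else
    H5Oget_info_by_idx(grp.id, ".", H5_INDEX_NAME, H5_ITER_INC, i, &oinfo,
                       H5P_DEFAULT);
#endif
    isgrp[(R_xlen_t)i] = (oinfo.type == H5O_TYPE_GROUP);
  }
  return List::create(_["name"] = names, _["is_group"] = isgrp);
}

// [[Rcpp::export(name = ".h5_exists")]]
bool h5_exists(std::string file, std::string path) {
  silence_errors();
  hid_t fid = H5Fopen(file.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (fid < 0) return false;
  bool ok = path_exists(fid, path);
  H5Fclose(fid);
  return ok;
}

// [[Rcpp::export(name = ".h5_is_group")]]
bool h5_is_group(std::string file, std::string path) {
  Hid fid(open_readonly(file), H5Fclose);
  if (!path_exists(fid.id, path)) stop("no such object: '%s'", path);
#if H5_VERSION_GE(1, 12, 0)
  H5O_info_t oinfo;
  H5Oget_info_by_name3(fid.id, path.c_str(), &oinfo, H5O_INFO_BASIC, H5P_DEFAULT);
#else
  H5O_info_t oinfo;
  H5Oget_info_by_name(fid.id, path.c_str(), &oinfo, H5P_DEFAULT);
#endif
  return oinfo.type == H5O_TYPE_GROUP;
}

// [[Rcpp::export(name = ".h5_delete")]]
void h5_delete(std::string file, std::string path) {
  Hid fid(open_or_create(file), H5Fclose);
  remove_if_exists(fid.id, path);
}

// [[Rcpp::export(name = ".h5_create")]]
void h5_create(std::string file) {
  silence_errors();
  hid_t fid = H5Fcreate(file.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  if (fid < 0) stop("cannot create HDF5 file '%s'", file);
  H5Fclose(fid);
}
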