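<?xml version="1.0" encoding="UTF-8"?>
<!-- Subset of the ProXL cross-link results import schema covering the
     elements this package emits: linker declaration with linkable sites,
     search program + score declaration, reported peptides with linked
     positions, and PSM entries with scan references and scores. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">

  <xs:element name="proxl_input">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="linkers">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="linker" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="linkable_site" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:attribute name="site" type="xs:string" use="required"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                  <xs:attribute name="name" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="search_program">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="score" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="name" type="xs:string" use="required"/>
                  <xs:attribute name="direction" use="required">
                    <xs:simpleType>
                      <xs:restriction base="xs:string">
                        <xs:enumeration value="higher_is_better"/>
                        <xs:enumeration value="lower_is_better"/>
                      </xs:restriction>
                    </xs:simpleType>
                  </xs:attribute>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="name" type="xs:string" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="reported_peptides">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="reported_peptide" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="peptide" minOccurs="2" maxOccurs="2">
                      <xs:complexType>
                        <xs:attribute name="sequence" type="xs:string" use="required"/>
                        <xs:attribute name="linked_position" type="xs:positiveInteger" use="required"/>
                        <xs:attribute name="protein" type="xs:string" use="required"/>
                        <xs:attribute name="protein_position" type="xs:positiveInteger" use="required"/>
                      </xs:complexType>
                    </xs:element>
                    <xs:element name="psms">
                      <xs:complexType>
                        <xs:sequence>
                          <xs:element name="psm" maxOccurs="unbounded">
                            <xs:complexType>
                              <xs:attribute name="scan_number" type="xs:string" use="required"/>
                              <xs:attribute name="run" type="xs:string" use="required"/>
                              <xs:attribute name="precursor_charge" type="xs:positiveInteger" use="required"/>
                              <xs:attribute name="score" type="xs:decimal" use="required"/>
                            </xs:complexType>
                          </xs:element>
                        </xs:sequence>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                  <xs:attribute name="reported_peptide_string" type="xs:string" use="required"/>
                  <xs:attribute name="type" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="fasta_filename" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
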