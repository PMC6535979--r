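<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">
  <xs:simpleType name="nonEmptyString">
    <xs:restriction base="xs:string">
      <xs:minLength value="1"/>
    </xs:restriction>
  </xs:simpleType>
  <xs:element name="decisionSupportRule">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="action">
          <xs:simpleType>
            <xs:restriction base="xs:string">
              <xs:enumeration value="Rule can be applied"/>
              <xs:enumeration value="Rule cannot be applied"/>
            </xs:restriction>
          </xs:simpleType>
        </xs:element>
        <xs:element name="condition">
          <xs:complexType>
            <xs:attribute name="value" type="nonEmptyString" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="moduleMetadata">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="title" type="xs:string"/>
              <xs:element name="authors" type="xs:string"/>
              <xs:element name="year" type="xs:string"/>
              <xs:element name="evidenceKind" type="xs:string"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="library" type="nonEmptyString"/>
        <xs:element name="trigger" type="xs:string"/>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
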